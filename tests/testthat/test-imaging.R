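# Nucleus/chromocenter segmentation, intensity quantification, binning,
# decondensation proxy, colocalization and line profiles.

test_that("a single disk nucleus is measured and passes the filters", {
  fx <- disk_field(radius_um = 5)
  seg <- segment_nuclei(fx$field)
  expect_equal(nrow(seg$nuclei), 1L)
  rec <- seg$nuclei[1, ]
  expect_equal(rec$area_um2, 25 * pi, tolerance = 0.02)
  expect_gt(rec$roundness, 0.9)
  expect_false(rec$touches_border)
  expect_true(rec$passes_filters)
})

test_that("the area filter excludes oversized nuclei (radius 10 um disk)", {
  fx <- disk_field(radius_um = 10, size_px = 512)
  seg <- segment_nuclei(fx$field)
  expect_equal(seg$nuclei$area_um2[1], 100 * pi, tolerance = 0.02)
  expect_false(seg$nuclei$passes_filters[1])
})

test_that("border-touching nuclei are flagged and excluded", {
  dapi <- matrix(10, 64, 64)
  dapi[1:20, 30:45] <- 500     # blob touching row 1
  f <- image_field(list(DAPI = dapi), 0.3)
  seg <- segment_nuclei(f, min_area_px = 10)
  expect_true(seg$nuclei$touches_border[1])
  expect_false(seg$nuclei$passes_filters[1])
})

test_that("segmentation survivor count equals the truth-table count", {
  sim <- make_nucleus_field(16, seed = 42)
  seg <- segment_nuclei(sim$field)
  expect_equal(sum(seg$nuclei$passes_filters),
               sum(sim$truth$params$nuclei$passes_filters))
})

test_that("measured areas are resolution-consistent (2x resampling)", {
  fx <- disk_field(radius_um = 5, pixel_size_um = 0.4, size_px = 128)
  a1 <- segment_nuclei(fx$field)$nuclei$area_um2[1]
  up <- fx$field$channels$DAPI[rep(seq_len(128), each = 2),
                               rep(seq_len(128), each = 2)]
  a2 <- segment_nuclei(image_field(list(DAPI = up), 0.2))$nuclei$area_um2[1]
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("chromocenters are confined to nuclei and conserve intensity", {
  fx <- disk_field(radius_um = 5, pixel_size_um = 0.2, size_px = 256)
  dapi <- fx$field$channels$DAPI
  x <- matrix(rep(seq_len(256), 256), 256); y <- t(x)
  spot <- 800 * exp(-((x - 128)^2 + (y - 120)^2) / (2 * 2^2))
  dapi_in <- dapi + spot * fx$mask
  f_in <- image_field(list(DAPI = dapi_in), 0.2)
  seg <- segment_nuclei(f_in, threshold_method = "fixed", threshold = 250)
  # a second bright spot entirely outside the nuclear mask is never reported
  dapi_out <- dapi_in + 800 * exp(-((x - 20)^2 + (y - 20)^2) / (2 * 2^2))
  f_out <- image_field(list(DAPI = dapi_out), 0.2)
  cc <- segment_chromocenters(f_out, seg$mask, spot_threshold = 600)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$parent_nucleus, 1L)
  # conservation: chromocenter sum cannot exceed its nucleus' sum
  expect_lte(cc$sum_DAPI[1], seg$nuclei$sum_DAPI[1])
  # nothing above threshold -> empty table
  cc0 <- segment_chromocenters(f_out, seg$mask, spot_threshold = 1e6)
  expect_equal(nrow(cc0), 0L)
})

test_that("a synthetic spot's measured sum is close to its rendered total", {
  fx <- disk_field(radius_um = 6, pixel_size_um = 0.2, size_px = 256,
                   level = 100)
  x <- matrix(rep(seq_len(256), 256), 256); y <- t(x)
  spot <- 900 * exp(-((x - 128)^2 + (y - 128)^2) / (2 * 2^2))
  dapi <- fx$field$channels$DAPI + spot
  f <- image_field(list(DAPI = dapi), 0.2)
  seg <- segment_nuclei(f, threshold_method = "fixed", threshold = 50)
  cc <- segment_chromocenters(f, seg$mask, spot_threshold = 130)
  spot_truth <- sum((spot + 100)[spot > 30])
  expect_equal(cc$sum_DAPI[1], spot_truth, tolerance = 0.02)
})

test_that("normalization to the control median behaves as a ratio", {
  rec <- data.frame(label_id = 1:4, sum_GFP = c(10, 20, 30, 40))
  ctrl <- data.frame(label_id = 1:3, sum_GFP = c(20, 20, 20))
  out <- measure_and_normalize(rec, "GFP", ctrl)
  expect_equal(out$norm_GFP, c(0.5, 1, 1.5, 2))
  doubled <- measure_and_normalize(
    transform(rec, sum_GFP = sum_GFP * 2), "GFP",
    transform(rec, sum_GFP = sum_GFP))
  expect_equal(doubled$norm_GFP[1], rec$sum_GFP[1] * 2 / median(rec$sum_GFP))
  expect_error(measure_and_normalize(rec, "GFP", ctrl[0, ]), "empty")
  expect_error(measure_and_normalize(rec, "GFP",
    data.frame(sum_GFP = c(0, 0))), "zero")
})

test_that("expression binning follows the half-open group bounds", {
  rec <- data.frame(sum_GFP = c(99.9, 100, 5000, 450, 999.99, 1000, -5))
  out <- bin_by_expression(rec, "GFP")
  expect_equal(out$expression_group,
               c("a", "b", "4", "b", "c", "2", "unbinned"))
})

test_that("decondensation index is the population SD of nuclear DAPI", {
  m <- matrix(10, 10, 10)
  f <- image_field(list(DAPI = m), 0.2)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(decondensation_index(f, mask), 0)
  m2 <- matrix(c(rep(10, 50), rep(30, 50)), 10, 10)
  expect_equal(decondensation_index(image_field(list(DAPI = m2), 0.2), mask), 10)
  # condensed (spotty) texture scores higher than flattened texture
  set.seed(2)
  flat <- matrix(100 + rnorm(400, 0, 2), 20, 20)
  spotty <- flat; spotty[sample(400, 40)] <- 400
  msk <- matrix(TRUE, 20, 20)
  expect_gt(decondensation_index(image_field(list(DAPI = spotty), 0.2), msk),
            decondensation_index(image_field(list(DAPI = flat), 0.2), msk))
  expect_error(decondensation_index(f, matrix(c(TRUE, rep(FALSE, 99)), 10)),
               ">= 2")
})

test_that("Pearson colocalization hits its closed-form extremes and null", {
  set.seed(3)
  a <- matrix(rnorm(10000, 100, 20), 100, 100)
  mask <- matrix(TRUE, 100, 100)
  f1 <- image_field(list(DAPI = a, X = a), 1)
  expect_equal(pearson_coloc(f1, "DAPI", "X", mask), 1)
  f2 <- image_field(list(DAPI = a, X = -a + 500), 1)
  expect_equal(pearson_coloc(f2, "DAPI", "X", mask), -1)
  b <- matrix(rnorm(10000, 100, 20), 100, 100)
  f3 <- image_field(list(DAPI = a, X = b), 1)
  expect_lt(abs(pearson_coloc(f3, "DAPI", "X", mask)), 0.05)
  f4 <- image_field(list(DAPI = a, X = matrix(7, 100, 100)), 1)
  expect_error(pearson_coloc(f4, "DAPI", "X", mask), "constant")
})

test_that("line profiles interpolate correctly and use calibrated distances", {
  m <- matrix(42, 64, 64)
  f <- image_field(list(DAPI = m), 0.2)
  pr <- line_profile(f, c(32, 10), c(32, 20))
  expect_true(all(pr$DAPI == 42))
  expect_equal(max(pr$distance_um), 10 * 0.2)
  # peak position through a Gaussian spot within 1 px of its center
  x <- matrix(rep(seq_len(64), 64), 64); y <- t(x)
  g <- exp(-((x - 30)^2 + (y - 40)^2) / (2 * 3^2))
  fg <- image_field(list(DAPI = g), 0.2)
  pr2 <- line_profile(fg, c(30, 20), c(30, 60))
  peak_col <- 20 + (which.max(pr2$DAPI) - 1) * (60 - 20) / (nrow(pr2) - 1)
  expect_lt(abs(peak_col - 40), 1)
  expect_error(line_profile(f, c(1, 1), c(1, 1)), "zero-length")
  expect_error(line_profile(f, c(0, 1), c(10, 10)), "inside")
})
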