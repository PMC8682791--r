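# Band integration, background dialects, ratios and the assay-specific
# quantities (MNase monomer ratio, +/-DDK replication signal, transcript
# normalization).

two_band_lane <- function(areas = c(20, 80), noise_sd = 0, level = 0) {
  make_gel_lanes(data.frame(position = c(100, 280), width = c(8, 10),
                            area = areas),
                 background = list(level = level, slope = 0),
                 noise_sd = noise_sd, seed = 3)
}

test_that("a pure Gaussian band integrates to its area within 1%", {
  sim <- make_gel_lanes(data.frame(position = 200, width = 10, area = 100),
                        background = list(level = 0, slope = 0))
  q <- integrate_band(sim$lanes[[1]], "band1", background_method = "none")
  expect_equal(q$raw_area, 100, tolerance = 0.01)
  # flat profile over flat background nets zero
  lane <- gel_lane(0:100, rep(5, 101), list(w = c(20, 60)))
  expect_equal(integrate_band(lane, "w", "flat")$net_area, 0)
  expect_error(integrate_band(lane, c(90, 120)), "outside")
})

test_that("background dialects: linear endpoints handle sloped gels", {
  x <- 0:200
  y <- 2 + 0.05 * x + 50 / (4 * sqrt(2 * pi)) * exp(-(x - 100)^2 / (2 * 16))
  lane <- gel_lane(x, y, list(band = c(80, 120)))
  q <- integrate_band(lane, "band", "linear-endpoints")
  expect_equal(q$net_area, 50, tolerance = 0.02)
})

test_that("negative net areas clip to zero with a flag", {
  lane <- gel_lane(0:100, c(seq(10, 0, length.out = 51),
                            seq(0.2, 10, length.out = 50)),
                   list(dip = c(30, 70)))
  q <- integrate_band(lane, "dip", "linear-endpoints")
  expect_equal(q$net_area, 0)
  expect_true(q$clipped)
})

test_that("lane linearity: scaling intensities scales areas, not ratios", {
  sim <- two_band_lane()
  lane <- sim$lanes[[1]]
  lane_k <- gel_lane(lane$positions, lane$intensity * 3, lane$band_windows)
  q1 <- integrate_band(lane, "band1")
  q1k <- integrate_band(lane_k, "band1")
  expect_equal(q1k$net_area, 3 * q1$net_area, tolerance = 1e-9)
  expect_equal(mnase_monomer_ratio(lane_k, "band1"),
               mnase_monomer_ratio(lane, "band1"), tolerance = 1e-12)
})

test_that("window partition additivity holds to 1%", {
  sim <- two_band_lane()
  lane <- sim$lanes[[1]]
  parts <- list(c(0, 150), c(150, 300), c(300, 400))
  whole <- integrate_band(lane, c(0, 400), "none")$raw_area
  total <- sum(vapply(parts, function(w)
    integrate_band(lane, w, "none")$raw_area, 1))
  expect_equal(total, whole, tolerance = 0.01)
})

test_that("noisy lanes recover true band areas within 5%", {
  sim <- two_band_lane(areas = c(40, 120), noise_sd = 0.03, level = 1)
  lane <- sim$lanes[[1]]
  tr <- sim$truth$params$true_areas[[1]]
  q1 <- integrate_band(lane, "band1")
  q2 <- integrate_band(lane, "band2")
  expect_lt(abs(q1$net_area / tr[1] - 1), 0.05)
  expect_lt(abs(q2$net_area / tr[2] - 1), 0.05)
})

test_that("ratio to control: self is 1, halved band is 0.5", {
  q <- data.frame(id = c("ctrl", "half"), net_area = c(10, 5))
  out <- ratio_to_control(q, "ctrl")
  expect_equal(out$normalized, c(1, 0.5))
  expect_error(ratio_to_control(data.frame(id = "a", net_area = 0), "a"), "> 0")
  # an exonuclease titration with decreasing truth stays monotone decreasing
  sim <- make_gel_lanes(lapply(c(100, 80, 55, 30, 10), function(a)
    data.frame(position = 200, width = 10, area = a)),
    background = list(level = 1, slope = 0), noise_sd = 0.02, seed = 8)
  nets <- vapply(sim$lanes, function(l) integrate_band(l, "band1")$net_area, 1)
  qd <- ratio_to_control(data.frame(id = seq_along(nets), net_area = nets), 1)
  expect_true(all(diff(qd$normalized) < 0))
})

test_that("MNase monomer/total ratio follows the band composition", {
  solo <- make_gel_lanes(data.frame(position = 200, width = 8, area = 50),
                         background = list(level = 0, slope = 0))
  expect_equal(mnase_monomer_ratio(solo$lanes[[1]], "band1"), 1,
               tolerance = 0.01)
  duo <- two_band_lane(areas = c(20, 80))
  expect_equal(mnase_monomer_ratio(duo$lanes[[1]], "band1"), 0.2,
               tolerance = 0.01)
  # ratio rises with digestion (increasing monomer share)
  series <- lapply(c(5, 20, 50, 80), function(m)
    make_gel_lanes(data.frame(position = c(100, 280), width = c(8, 10),
                              area = c(m, 100 - m)),
                   background = list(level = 0, slope = 0))$lanes[[1]])
  ratios <- vapply(series, mnase_monomer_ratio, 1, monomer_window = "band1")
  expect_true(all(diff(ratios) > 0))
})

test_that("replication signal subtracts the -DDK control and normalizes to dC", {
  mk <- function(area, template) {
    sim <- make_gel_lanes(data.frame(position = 150, width = 12, area = area),
                          background = list(level = 0.5, slope = 0))
    lane <- sim$lanes[[1]]
    lane$lane_meta$template <- template
    lane
  }
  # identical +/- lanes cancel exactly
  l <- mk(60, "dC")
  expect_equal(replication_signal(l, l, "band1"), 0)
  # truth dC:1.0, 5mC:0.6, 5hmC:0.9 (relative incorporation) is recovered
  minus <- list(dC = mk(5, "dC"), `5mC` = mk(5, "5mC"), `5hmC` = mk(5, "5hmC"))
  plus <- list(dC = mk(105, "dC"), `5mC` = mk(65, "5mC"), `5hmC` = mk(95, "5hmC"))
  sig <- vapply(names(plus), function(tp)
    replication_signal(plus[[tp]], minus[[tp]], "band1"), 1)
  norm <- normalize_to_template(sig, "dC")
  expect_equal(unname(norm["dC"]), 1)
  expect_true(norm[["5mC"]] < norm[["5hmC"]] && norm[["5hmC"]] < norm[["dC"]])
  expect_error(replication_signal(mk(10, "dC"), mk(10, "5mC"), "band1"),
               "unmatched")
})

test_that("transcript intensities normalize to the reference and saturate", {
  mk <- function(area) make_gel_lanes(
    data.frame(position = 150, width = 12, area = area),
    background = list(level = 0, slope = 0))$lanes[[1]]
  ref_lane <- mk(80)
  ref <- integrate_band(ref_lane, "band1")$net_area
  expect_equal(transcript_normalized_intensity(ref_lane, "band1", ref), 1,
               tolerance = 1e-9)
  empty <- gel_lane(0:300, rep(0, 301), list(band1 = c(114, 186)))
  expect_equal(transcript_normalized_intensity(empty, "band1", ref), 0)
  # saturating time course stays non-decreasing after normalization
  tc <- vapply(c(10, 30, 55, 70, 78, 80), function(a)
    transcript_normalized_intensity(mk(a), "band1", ref), 1)
  expect_true(all(diff(tc) >= 0))
  expect_error(transcript_normalized_intensity(ref_lane, "band1", 0), "> 0")
})
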