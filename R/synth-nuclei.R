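# Synthetic nucleus fields with recorded ground truth. Nuclei are rendered
# as ellipses on a grid of non-overlapping cells; deliberate fractions fail
# the geometry filters (too small, too large, elongated, border-touching) so
# the filter rule can be validated against the truth table.

ellipse_roundness <- function(a, b) {
  # analytic 4*pi*A/P^2 with Ramanujan's perimeter approximation, clipped at 1
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  min(1, 4 * pi * (pi * a * b) / P^2)
}

#' Simulate a calibrated nucleus field with ground truth
#'
#' Renders `n_nuclei` elliptical nuclei on a DAPI background, one per grid
#' cell so masks never merge. Per `shape_params`, set fractions of nuclei are
#' drawn to clearly pass or clearly fail each geometry filter: `pass` (area
#' 80--260 um^2, near-circular), `small` (25--45 um^2), `large`
#' (330--420 um^2), `elongated` (aspect ratio 2.5--3.5, roundness well below
#' 0.8) and `border` (pass-shaped but centred on the field edge). Optional
#' DAPI-bright chromocenter spots (Gaussian, sigma 2 px) and an expression
#' channel (`GFP`, lognormal per-nucleus level) are added. The truth table
#' records every nucleus' analytic area and roundness, border contact,
#' noiseless channel sums and filter verdict.
#'
#' @param n_nuclei Number of nuclei (>= 1).
#' @param pixel_size_um Pixel size in micrometres.
#' @param shape_params Named fractions `pass`, `small`, `large`, `elongated`,
#'   `border` summing to 1.
#' @param channel_model List; `GFP = c(meanlog, sdlog)` of the lognormal
#'   per-nucleus expression level (a.u. per pixel).
#' @param n_chromocenters Spots per nucleus (0 disables).
#' @param noise_sd SD of additive Gaussian read noise on every channel.
#' @param field_px Optional canvas size (square). Rejected if too small to
#'   place the nuclei without overlap.
#' @param seed Integer seed.
#' @return List with `field` (an [image_field()]) and `truth` (a `sim_truth`
#'   whose `params$nuclei` data frame holds the per-nucleus ground truth).
#' @export
make_nucleus_field <- function(n_nuclei, pixel_size_um = 0.32,
                               shape_params = c(pass = 0.5, small = 0.1,
                                                large = 0.1, elongated = 0.15,
                                                border = 0.15),
                               channel_model = list(GFP = c(meanlog = -0.85, sdlog = 1.0)),
                               n_chromocenters = 4, noise_sd = 5,
                               field_px = NULL, seed = 1) {
  assert_scalar_num(n_nuclei, "n_nuclei", lower = 1)
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  req <- c("pass", "small", "large", "elongated", "border")
  if (!all(req %in% names(shape_params)) ||
      abs(sum(shape_params) - 1) > 1e-8)
    stopf("shape_params must be fractions over {%s} summing to 1",
          paste(req, collapse = ", "))
  set.seed(seed)

  # grid cells sized for the largest possible nucleus
  max_a_um <- sqrt(420 * 3.5 / pi)              # largest semi-major axis, um
  cell_px <- ceiling(2 * max_a_um / pixel_size_um) + 6L
  g <- ceiling(sqrt(n_nuclei))
  canvas <- g * cell_px
  if (!is.null(field_px)) {
    if (field_px < canvas)
      stopf("field of %d px is too small to place %d nuclei without overlap (need %d)",
            field_px, n_nuclei, canvas)
    canvas <- field_px
    g <- canvas %/% cell_px
  }

  category <- sample(req, n_nuclei, replace = TRUE, prob = shape_params[req])
  # assign cells: border nuclei need edge cells
  all_cells <- expand.grid(gr = seq_len(g), gc = seq_len(g))
  edge <- all_cells$gr %in% c(1L, g) | all_cells$gc %in% c(1L, g)
  n_border <- sum(category == "border")
  if (n_border > sum(edge))
    stopf("field too small: %d border nuclei but only %d edge cells",
          n_border, sum(edge))
  cells <- integer(n_nuclei)
  cells[category == "border"] <- sample(which(edge), n_border)
  pool <- setdiff(seq_len(nrow(all_cells)), cells[category == "border"])
  cells[category != "border"] <- sample(pool, n_nuclei - n_border)

  dapi <- matrix(20, canvas, canvas)
  gfp <- matrix(0.02, canvas, canvas)
  xg <- matrix(rep(seq_len(canvas), canvas), canvas)
  yg <- t(xg)
  truth <- vector("list", n_nuclei)
  spots_per_nuc <- list()

  for (i in seq_len(n_nuclei)) {
    cat_i <- category[i]
    area_um2 <- switch(cat_i,
      pass = stats::runif(1, 80, 260), border = stats::runif(1, 80, 260),
      small = stats::runif(1, 25, 45), large = stats::runif(1, 330, 420),
      elongated = stats::runif(1, 80, 260))
    aspect <- switch(cat_i, elongated = stats::runif(1, 2.5, 3.5),
                     stats::runif(1, 1.0, 1.25))
    a_um <- sqrt(area_um2 * aspect / pi)
    b_um <- a_um / aspect
    a_px <- a_um / pixel_size_um
    b_px <- b_um / pixel_size_um
    phi <- stats::runif(1, 0, pi)
    gr <- all_cells$gr[cells[i]]; gc <- all_cells$gc[cells[i]]
    c0 <- c((gr - 1) * cell_px + cell_px / 2, (gc - 1) * cell_px + cell_px / 2)
    slack <- cell_px / 2 - a_px - 2
    if (cat_i == "border") {
      # center placed on the nearest canvas edge so the mask is cut off
      if (gr %in% c(1L, g) ) c0[1] <- if (gr == 1L) 1 else canvas
      else c0[2] <- if (gc == 1L) 1 else canvas
      if (gr == 1L && gc %in% c(1L, g)) c0[1] <- 1
    } else if (slack > 0) {
      c0 <- c0 + stats::runif(2, -slack, slack)
    }
    dx <- xg - c0[1]; dy <- yg - c0[2]
    u <- (dx * cos(phi) + dy * sin(phi)) / a_px
    v <- (-dx * sin(phi) + dy * cos(phi)) / b_px
    sel <- u^2 + v^2 <= 1
    dapi_level <- stats::runif(1, 450, 550)
    gfp_level <- stats::rlnorm(1, channel_model$GFP["meanlog"],
                               channel_model$GFP["sdlog"])
    dapi[sel] <- dapi_level
    gfp[sel] <- gfp_level
    # chromocenter spots well inside the nucleus
    if (n_chromocenters > 0 && cat_i != "border") {
      for (s in seq_len(n_chromocenters)) {
        ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, 0.55)
        sc <- c0 + rad * c(a_px * cos(phi) * cos(ang) - b_px * sin(phi) * sin(ang),
                           a_px * sin(phi) * cos(ang) + b_px * cos(phi) * sin(ang))
        amp <- stats::runif(1, 700, 900)
        spot <- amp * exp(-((xg - sc[1])^2 + (yg - sc[2])^2) / (2 * 2^2))
        near <- abs(xg - sc[1]) < 10 & abs(yg - sc[2]) < 10
        dapi[near] <- dapi[near] + spot[near]
      }
    }
    touches <- cat_i == "border"
    roundness <- ellipse_roundness(a_um, b_um)
    truth[[i]] <- data.frame(
      nucleus = i, category = cat_i, center_row = c0[1], center_col = c0[2],
      a_um = a_um, b_um = b_um, area_um2 = pi * a_um * b_um,
      roundness = roundness, touches_border = touches,
      sum_DAPI = sum(dapi[sel]), sum_GFP = sum(gfp[sel]),
      dapi_level = dapi_level, gfp_level = gfp_level)
  }
  truth <- do.call(rbind, truth)
  truth$passes_filters <- truth$roundness > 0.8 &
    truth$area_um2 >= 60 & truth$area_um2 <= 300 & !truth$touches_border

  if (noise_sd > 0) {
    # DAPI carries camera-scale read noise; the expression channel is on a
    # much lower intensity scale, so its noise is scaled accordingly
    dapi <- pmax(dapi + stats::rnorm(length(dapi), 0, noise_sd), 0)
    gfp <- pmax(gfp + stats::rnorm(length(gfp), 0, noise_sd / 100), 0)
  }
  field <- image_field(list(DAPI = dapi, GFP = gfp), pixel_size_um)
  list(field = field,
       truth = sim_truth("make_nucleus_field", seed,
                         list(nuclei = truth, noise_sd = noise_sd,
                              shape_params = shape_params)))
}
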