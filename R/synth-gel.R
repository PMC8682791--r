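# Synthetic gel lanes: Gaussian bands on a smooth background with recorded
# true band areas.

#' Simulate gel lane profiles
#'
#' Each lane is a 1-D profile `background + sum of Gaussian bands + noise`;
#' a band with `area` A, `position` m and `width` s contributes
#' `A / (s * sqrt(2*pi)) * exp(-(x - m)^2 / (2 s^2))`, so its integral is A.
#' Bands whose +/-3 sigma windows overlap are flagged in the truth record.
#'
#' @param band_spec List of lane specifications; each a data frame with
#'   columns `position`, `width`, `area` (areas >= 0), one row per band.
#' @param background List with `level` (constant offset) and `slope`
#'   (linear drift per position unit).
#' @param noise_sd SD of additive Gaussian profile noise.
#' @param n_points Number of profile points.
#' @param length_px Profile length (positions run 0..length_px).
#' @param seed Integer seed.
#' @return List with `lanes` (list of [gel_lane()], windows set to each
#'   band's +/-3 sigma interval) and `truth` (`sim_truth` with per-lane true
#'   areas and overlap flags).
#' @export
make_gel_lanes <- function(band_spec, background = list(level = 2, slope = 0),
                           noise_sd = 0, n_points = 800, length_px = 400,
                           seed = 1) {
  if (is.data.frame(band_spec)) band_spec <- list(band_spec)
  set.seed(seed)
  x <- seq(0, length_px, length.out = n_points)
  lanes <- vector("list", length(band_spec))
  truth_areas <- vector("list", length(band_spec))
  overlaps <- logical(length(band_spec))
  for (i in seq_along(band_spec)) {
    bs <- band_spec[[i]]
    stopifnot(all(c("position", "width", "area") %in% names(bs)))
    if (any(bs$area < 0)) stopf("band areas must be >= 0")
    y <- background$level + (background$slope %||% 0) * x
    wins <- list()
    for (j in seq_len(nrow(bs))) {
      y <- y + bs$area[j] / (bs$width[j] * sqrt(2 * pi)) *
        exp(-(x - bs$position[j])^2 / (2 * bs$width[j]^2))
      wins[[sprintf("band%d", j)]] <- c(max(0, bs$position[j] - 4 * bs$width[j]),
                                        min(length_px, bs$position[j] + 4 * bs$width[j]))
    }
    if (nrow(bs) > 1L) {
      o <- order(bs$position)
      lo <- bs$position[o] - 4 * bs$width[o]
      hi <- bs$position[o] + 4 * bs$width[o]
      overlaps[i] <- any(lo[-1] < hi[-length(hi)])
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    lanes[[i]] <- gel_lane(x, y, wins, lane_meta = list(lane = i))
    truth_areas[[i]] <- bs$area
  }
  list(lanes = lanes,
       truth = sim_truth("make_gel_lanes", seed,
                         list(true_areas = truth_areas,
                              overlapping_windows = overlaps,
                              background = background, noise_sd = noise_sd)))
}
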