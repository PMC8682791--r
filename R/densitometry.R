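# Gel/blot lane densitometry: trapezoidal band integration with background
# subtraction, ratio-to-control normalization, the MNase monomer/total
# ratio, +/-DDK replication-signal subtraction and transcript normalization.

#' Construct a gel lane profile
#'
#' @param positions Ascending migration coordinates (px or mm).
#' @param intensity Non-negative intensity profile, same length.
#' @param band_windows Named list of `c(start, end)` position intervals.
#' @param lane_meta Named list of condition labels (template, enzyme units,
#'   +/-DDK, timepoint, ...).
#' @return A `gel_lane` object.
#' @export
gel_lane <- function(positions, intensity, band_windows = list(),
                     lane_meta = list()) {
  stopifnot(length(positions) == length(intensity))
  if (is.unsorted(positions, strictly = TRUE))
    stopf("positions must be strictly ascending")
  rng <- range(positions)
  for (w in band_windows)
    if (w[1] < rng[1] || w[2] > rng[2] || w[1] >= w[2])
      stopf("band window [%g, %g) outside the profile or empty", w[1], w[2])
  structure(list(positions = positions, intensity = intensity,
                 band_windows = band_windows, lane_meta = lane_meta),
            class = "gel_lane")
}

lane_window <- function(lane, window) {
  w <- if (is.character(window)) {
    if (!window %in% names(lane$band_windows))
      stopf("unknown band window `%s`", window)
    lane$band_windows[[window]]
  } else window
  rng <- range(lane$positions)
  if (w[1] < rng[1] || w[2] > rng[2]) stopf("window outside the profile")
  w
}

lane_integral <- function(lane, w = NULL) {
  sel <- if (is.null(w)) rep(TRUE, length(lane$positions))
         else lane$positions >= w[1] & lane$positions <= w[2]
  if (sum(sel) < 2L) stopf("window covers < 2 profile points")
  pracma::trapz(lane$positions[sel], lane$intensity[sel])
}

#' Integrate a band with background subtraction
#'
#' Raw area is the trapezoidal integral of the profile over the window.
#' Background: `"linear-endpoints"` (default) integrates the straight line
#' joining the window's endpoint intensities, each estimated as the mean of
#' the `endpoint_pts` outermost profile points (robust for sloped, noisy gel
#' backgrounds and exact for linear ones); `"flat"` uses the window's minimum
#' intensity times its width. Negative net areas are clipped to 0 and
#' flagged.
#'
#' @param lane A [gel_lane()].
#' @param window Window name or numeric `c(start, end)`.
#' @param background_method `"linear-endpoints"`, `"flat"`, or `"none"`.
#' @param endpoint_pts Points averaged at each window end for the
#'   linear-endpoints background.
#' @return One-row data frame: `raw_area`, `background`, `net_area`,
#'   `clipped`.
#' @export
integrate_band <- function(lane, window,
                           background_method = c("linear-endpoints", "flat", "none"),
                           endpoint_pts = 3L) {
  background_method <- match.arg(background_method)
  w <- lane_window(lane, window)
  sel <- lane$positions >= w[1] & lane$positions <= w[2]
  if (sum(sel) < 2L) stopf("window covers < 2 profile points")
  x <- lane$positions[sel]; y <- lane$intensity[sel]
  raw <- pracma::trapz(x, y)
  k <- min(endpoint_pts, floor(length(y) / 2))
  bg <- switch(background_method,
    `linear-endpoints` = {
      # straight line through the averaged endpoint anchors, integrated over
      # the window span (exact for a linear background)
      xl <- mean(x[seq_len(k)]); yl <- mean(y[seq_len(k)])
      xr <- mean(x[seq(length(x) - k + 1L, length(x))])
      yr <- mean(y[seq(length(y) - k + 1L, length(y))])
      slope <- if (xr > xl) (yr - yl) / (xr - xl) else 0
      mid <- yl + slope * ((x[1] + x[length(x)]) / 2 - xl)
      mid * (x[length(x)] - x[1])
    },
    flat = min(y) * (x[length(x)] - x[1]),
    none = 0)
  net <- raw - bg
  data.frame(raw_area = raw, background = bg, net_area = max(0, net),
             clipped = net < 0)
}

#' Normalize band quantifications to a control
#'
#' Divides each net area by the control's net area ("plotted as a ratio to
#' the control").
#'
#' @param quants Data frame with `net_area` and an identifier column `id`.
#' @param control_id Identifier of the control row.
#' @return `quants` with an added `normalized` column.
#' @export
ratio_to_control <- function(quants, control_id) {
  stopifnot(all(c("id", "net_area") %in% names(quants)))
  ctrl <- quants$net_area[quants$id == control_id]
  if (length(ctrl) != 1L) stopf("control `%s` not found exactly once", control_id)
  if (ctrl <= 0) stopf("control net area must be > 0")
  quants$normalized <- quants$net_area / ctrl
  quants
}

#' MNase accessibility: mononucleosome / total DNA ratio
#'
#' Raw integrated intensity of the monomer band window divided by the raw
#' integral of the whole lane.
#'
#' @param lane A [gel_lane()].
#' @param monomer_window Window name or `c(start, end)`.
#' @return The monomer/total ratio.
#' @export
mnase_monomer_ratio <- function(lane, monomer_window) {
  w <- lane_window(lane, monomer_window)
  total <- lane_integral(lane)
  if (total <= 0) stopf("total lane intensity is zero")
  lane_integral(lane, w) / total
}

#' Net replication signal from a matched +/-DDK lane pair
#'
#' Integrates the signal below the end-labelling band (the `below_window`) in
#' the +DDK lane, subtracts the matched -DDK lane's signal (the
#' no-initiation control), both background-corrected. The lanes must carry
#' the same template label in `lane_meta$template` when present.
#'
#' @param lane_plus,lane_minus_ddk Matched [gel_lane()]s (+DDK and -DDK).
#' @param below_window Window name or `c(start, end)` covering the signal
#'   below the end-labelling band.
#' @param background_method Passed to [integrate_band()].
#' @return Net replication signal (a.u., can be 0 for identical lanes).
#' @export
replication_signal <- function(lane_plus, lane_minus_ddk, below_window,
                               background_method = "linear-endpoints") {
  tp <- lane_plus$lane_meta$template
  tm <- lane_minus_ddk$lane_meta$template
  if (!is.null(tp) && !is.null(tm) && !identical(tp, tm))
    stopf("unmatched templates: `%s` vs `%s`", tp, tm)
  qp <- integrate_band(lane_plus, below_window, background_method)
  qm <- integrate_band(lane_minus_ddk, below_window, background_method)
  qp$net_area - qm$net_area
}

#' Normalize replication signals to the unmodified-cytosine template
#'
#' @param signals Named numeric vector of net replication signals per
#'   template.
#' @param reference Name of the reference template (default `"dC"`).
#' @return `signals / signals[reference]`.
#' @export
normalize_to_template <- function(signals, reference = "dC") {
  if (!reference %in% names(signals))
    stopf("reference template `%s` missing", reference)
  if (signals[reference] <= 0) stopf("reference signal must be > 0")
  signals / signals[[reference]]
}

#' Transcript signal normalized to a reference intensity
#'
#' Background-subtracted full-length-transcript band area divided by a fixed
#' reference value (the unmodified-template full-length signal at the
#' reference timepoint).
#'
#' @param lane A [gel_lane()].
#' @param fulllength_window Window name or `c(start, end)`.
#' @param reference_value Reference intensity (> 0).
#' @param background_method Passed to [integrate_band()].
#' @return Normalized signal intensity (dimensionless).
#' @export
transcript_normalized_intensity <- function(lane, fulllength_window,
                                            reference_value,
                                            background_method = "linear-endpoints") {
  assert_scalar_num(reference_value, "reference_value", lower = 0, strict = TRUE)
  integrate_band(lane, fulllength_window, background_method)$net_area /
    reference_value
}
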