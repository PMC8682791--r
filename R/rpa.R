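# RPA accumulation kinetics: the coefficient of variation (cV = sigma/mu) of
# nuclear RPA signal as a helicase-speed proxy, normalized to the
# pretreatment frame, with the accumulation slope taken over the first
# 20 minutes of drug treatment to avoid plateau phases.

#' Coefficient of variation of masked pixel intensities
#'
#' `cV = sigma / mu` with sigma the population standard deviation and mu the
#' mean of the pixel intensities under the mask. Invariant under
#' multiplicative gain.
#'
#' @param frame Numeric matrix (one image frame) or an [image_field()]
#'   (its first channel is used).
#' @param mask Logical or 0/1 matrix, >= 10 selected pixels.
#' @return The cV value (dimensionless, >= 0).
#' @export
cv_of_region <- function(frame, mask) {
  if (inherits(frame, "image_field")) frame <- frame$channels[[1]]
  sel <- mask > 0
  if (sum(sel) < 10L) stopf("mask must contain >= 10 pixels")
  px <- frame[sel]
  mu <- mean(px)
  if (mu <= 0) stopf("mean intensity must be > 0 for cV")
  pop_sd(px) / mu
}

#' Build a normalized cV trajectory from a time-lapse stack
#'
#' Computes the nuclear cV for every frame and normalizes to the pretreatment
#' frame: `cv_norm(t) = cv_raw(t) / cv_raw(0)`, so the first value is exactly
#' 1.
#'
#' @param stack List with `frames` (list of matrices) and `times_min`
#'   (ascending, first = 0), as produced by [make_rpa_timelapse()].
#' @param masks A single mask reused for every frame (default `stack$mask`),
#'   or a list of per-frame masks.
#' @param treatment,stage Optional condition labels stored on the trajectory.
#' @return Data frame of class `cv_trajectory`: `time_min`, `cv_raw`,
#'   `cv_norm`, with `treatment` and `stage` attributes.
#' @export
build_trajectory <- function(stack, masks = NULL, treatment = NULL,
                             stage = NA_character_) {
  frames <- stack$frames
  times <- stack$times_min
  stopifnot(length(frames) == length(times))
  if (times[1] != 0) stopf("frame 0 must be the pretreatment image (t = 0)")
  masks <- masks %||% stack$mask
  if (!is.list(masks)) masks <- rep(list(masks), length(frames))
  cv_raw <- mapply(cv_of_region, frames, masks)
  if (cv_raw[1] == 0)
    stopf("pretreatment cV is zero (no texture); cannot normalize")
  out <- data.frame(time_min = times, cv_raw = cv_raw,
                    cv_norm = cv_raw / cv_raw[1])
  attr(out, "treatment") <- treatment %||% stack$treatment %||% NA_character_
  attr(out, "stage") <- stage
  class(out) <- c("cv_trajectory", "data.frame")
  out
}

#' Early-window slope of a normalized cV trajectory
#'
#' Ordinary least-squares line through `(t, cv_norm)` for all timepoints with
#' `t <= window_min` (default 20 min, excluding accumulation plateaus); the
#' slope is the regression coefficient, identical to rise-over-run of the
#' fitted line's endpoints.
#'
#' @param traj A `cv_trajectory` (or data frame with `time_min`, `cv_norm`).
#' @param window_min Upper time bound of the fit window, minutes.
#' @return One-row data frame: `slope` (normalized cV per minute),
#'   `window_min`, `n_points`.
#' @export
accumulation_slope <- function(traj, window_min = 20) {
  sel <- traj$time_min <= window_min
  if (sum(sel) < 3L)
    stopf("need >= 3 timepoints within [0, %g] min, got %d",
          window_min, sum(sel))
  fit <- stats::lm(cv_norm ~ time_min, data = traj[sel, , drop = FALSE])
  data.frame(slope = unname(stats::coef(fit)[2]), window_min = window_min,
             n_points = sum(sel))
}

#' Compare accumulation slopes between treatment conditions
#'
#' Per-condition mean and SD of the slopes plus pairwise equal-variance
#' t-tests (delegating to [compare_groups()]).
#'
#' @param slopes_by_condition Named list mapping condition to a numeric
#'   vector of slopes (>= 2 per condition).
#' @return List with `summary` (condition, n, mean_slope, sd_slope) and
#'   `tests` (condition_a, condition_b, delta_slope, p_value).
#' @export
compare_conditions <- function(slopes_by_condition) {
  if (length(slopes_by_condition) < 2L) stopf("need >= 2 conditions")
  if (any(vapply(slopes_by_condition, length, 1L) < 2L))
    stopf("each condition needs >= 2 slopes")
  conds <- names(slopes_by_condition)
  summ <- do.call(rbind, lapply(conds, function(cn) {
    x <- slopes_by_condition[[cn]]
    data.frame(condition = cn, n = length(x), mean_slope = mean(x),
               sd_slope = stats::sd(x), stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- slopes_by_condition[[pr[1]]]; b <- slopes_by_condition[[pr[2]]]
    data.frame(condition_a = pr[1], condition_b = pr[2],
               delta_slope = mean(a) - mean(b),
               p_value = compare_groups(a, b, test = "student_t")$p_value,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
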