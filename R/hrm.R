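# High-resolution melting (HRM) analysis: baseline normalization, smoothed
# negative derivative, Tm calling and group comparison.

check_melt_grid <- function(temp_C) {
  n <- length(temp_C)
  if (n < 50L) stopf("melt curve needs >= 50 points, got %d", n)
  d <- diff(temp_C)
  if (any(d <= 0)) stopf("temperature grid must be strictly ascending")
  if (max(d) - min(d) > 1e-6) stopf("temperature grid spacing is not uniform")
  invisible(mean(d))
}

#' Baseline-normalize a melting curve
#'
#' Fits linear pre-melt (upper) and post-melt (lower) baselines on the first
#' `pre_window` and last `post_window` fractions of the temperature grid, then
#' rescales fluorescence to the fraction of intact duplex:
#' `F' = (F - lower(T)) / (upper(T) - lower(T))`, clipped to `[0, 1]`.
#'
#' @param curve Data frame with columns `temp_C` and `fluor` (one curve).
#' @param pre_window,post_window Fractions of the grid used for the upper and
#'   lower baselines; each must cover at least 3 points and together < 1.
#' @return The curve with `fluor` replaced by the normalized values.
#' @export
normalize_melt <- function(curve, pre_window = 0.1, post_window = 0.1) {
  stopifnot(is.data.frame(curve), all(c("temp_C", "fluor") %in% names(curve)))
  check_melt_grid(curve$temp_C)
  n <- nrow(curve)
  n_pre <- floor(pre_window * n)
  n_post <- floor(post_window * n)
  if (n_pre < 3L || n_post < 3L)
    stopf("baseline windows must each cover >= 3 grid points")
  if (pre_window + post_window >= 1)
    stopf("pre_window + post_window must be < 1")
  pre <- seq_len(n_pre)
  post <- seq(n - n_post + 1L, n)
  up <- stats::lm(fluor ~ temp_C, data = curve[pre, ])
  lo <- stats::lm(fluor ~ temp_C, data = curve[post, ])
  upper <- stats::predict(up, curve)
  lower <- stats::predict(lo, curve)
  tol <- 1e-9 * max(abs(curve$fluor), 1)
  if (any(upper - lower <= tol))
    stopf("baselines cross or coincide inside the grid; curve is not a melt")
  f <- (curve$fluor - lower) / (upper - lower)
  curve$fluor <- pmin(1, pmax(0, f))
  curve
}

#' Smoothed negative derivative of a melting curve
#'
#' Replicates sharing the temperature grid are averaged point-wise, then a
#' Savitzky--Golay local-polynomial filter (order 3) estimates dF/dT; the sign
#' is flipped so a melt transition appears as a positive peak.
#'
#' @param curve Data frame with `temp_C` and `fluor`; may contain several
#'   replicates of one amplicon (any further columns are ignored).
#' @param smooth_window_pts Odd filter window length, >= 5 and shorter than
#'   the curve.
#' @return Data frame with `temp_C` and `minus_dF_dT`.
#' @export
derivative_melt <- function(curve, smooth_window_pts = 11) {
  stopifnot(is.data.frame(curve), all(c("temp_C", "fluor") %in% names(curve)))
  mean_f <- tapply(curve$fluor, curve$temp_C, mean)
  temps <- as.numeric(names(mean_f))
  o <- order(temps)
  temps <- temps[o]
  f <- as.numeric(mean_f)[o]
  step <- check_melt_grid(temps)
  w <- smooth_window_pts
  if (w %% 2 == 0 || w < 5) stopf("smooth_window_pts must be odd and >= 5")
  if (w >= length(temps)) stopf("smoothing window must be shorter than the curve")
  df_dt <- signal::sgolayfilt(f, p = 3, n = w, m = 1, ts = step)
  data.frame(temp_C = temps, minus_dF_dT = -df_dt)
}

#' Call the melting temperature from a derivative curve
#'
#' The peak of `-dF/dT` is located as the global grid maximum (ties broken
#' toward the lowest temperature). With `refine = "centroid"` (default) the
#' reported Tm is the sub-grid peak position: the intensity-weighted centroid
#' of the contiguous derivative region around the maximum that lies above
#' half the peak height. For a symmetric melting peak the centroid coincides
#' with the true peak and is far less sensitive to fluorescence noise than
#' the raw grid argmax; `refine = "none"` reports the grid temperature
#' itself. Points inside the smoothing margin at either end are excluded
#' from the search; a maximum sitting on the search boundary is flagged as an
#' edge call.
#'
#' @param temps Temperature grid, degrees C.
#' @param minus_dF_dT Negative derivative values, same length.
#' @param exclude_pts Number of margin points excluded at each end (default
#'   half of the default 11-point smoothing window).
#' @param refine `"centroid"` (half-maximum centroid, default) or `"none"`
#'   (grid argmax).
#' @return Data frame (one row): `tm_C`, `peak_height`, `edge_call`.
#' @export
call_tm <- function(temps, minus_dF_dT, exclude_pts = 5L,
                    refine = c("centroid", "none")) {
  refine <- match.arg(refine)
  stopifnot(length(temps) == length(minus_dF_dT))
  n <- length(temps)
  if (n - 2L * exclude_pts < 3L) stopf("curve too short for Tm search")
  if (max(minus_dF_dT) - min(minus_dF_dT) <= 0)
    stopf("derivative is constant; no melting transition to call")
  idx <- seq(exclude_pts + 1L, n - exclude_pts)
  y <- minus_dF_dT[idx]
  k <- which.max(y)                # which.max takes the first = lowest T on ties
  i <- idx[k]
  edge <- k == 1L || k == length(idx)
  if (edge) warning("Tm maximum lies on the search boundary (edge call)")
  tm <- temps[i]
  if (refine == "centroid" && !edge) {
    th <- y[k] / 2
    above <- y >= th
    # contiguous above-half-max run containing the peak
    lo <- k; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- k; while (hi < length(y) && above[hi + 1L]) hi <- hi + 1L
    wgt <- y[lo:hi] - th
    tm <- sum(temps[idx[lo:hi]] * wgt) / sum(wgt)
  }
  data.frame(tm_C = tm, peak_height = y[k], edge_call = edge)
}

#' Full HRM pipeline over a long-format curve table
#'
#' Normalizes each curve, then calls Tm either once per label (`by =
#' "label"`, default: technical replicates are averaged point-wise before
#' differentiation, matching how replicate melt curves are reported) or once
#' per curve (`by = "curve"`, retaining replicate-level variation for group
#' tests).
#'
#' @param curves Long data frame (`curve_id`, `label`, `temp_C`, `fluor`).
#' @param by `"label"` (average replicates first) or `"curve"`.
#' @param smooth_window_pts Passed to [derivative_melt()].
#' @param pre_window,post_window Passed to [normalize_melt()].
#' @param refine Passed to [call_tm()].
#' @return Data frame with one row per label or per curve: `label`
#'   (`curve_id`), `tm_C`, `peak_height`, `edge_call`.
#' @export
hrm_call_tms <- function(curves, by = c("label", "curve"),
                         smooth_window_pts = 11,
                         pre_window = 0.1, post_window = 0.1,
                         refine = "centroid") {
  by <- match.arg(by)
  stopifnot(all(c("curve_id", "label", "temp_C", "fluor") %in% names(curves)))
  margin <- (smooth_window_pts - 1L) %/% 2L
  one <- function(cv, id_cols) {
    nms <- lapply(split(cv, cv$curve_id), function(d)
      normalize_melt(d[order(d$temp_C), ], pre_window, post_window))
    dv <- derivative_melt(do.call(rbind, nms), smooth_window_pts)
    tm <- call_tm(dv$temp_C, dv$minus_dF_dT, exclude_pts = margin,
                  refine = refine)
    cbind(id_cols, tm)
  }
  res <- if (by == "label") {
    lapply(split(curves, curves$label), function(cv)
      one(cv, data.frame(label = cv$label[1], stringsAsFactors = FALSE)))
  } else {
    lapply(split(curves, curves$curve_id), function(cv)
      one(cv, data.frame(curve_id = cv$curve_id[1], label = cv$label[1],
                         stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare called melting temperatures between modification groups
#'
#' For every pair of labels, reports the mean Tm difference and a two-group
#' Student's t-test p-value (delegating to [compare_groups()]).
#'
#' @param results_by_label Named list mapping each label to a numeric vector
#'   of called Tm values (or a data frame with a `tm_C` column).
#' @return Data frame: `label_a`, `label_b`, `n_a`, `n_b`, `delta_tm_C`
#'   (mean a - mean b), `p_value`.
#' @export
compare_tm_groups <- function(results_by_label) {
  vals <- lapply(results_by_label, function(x) {
    if (is.data.frame(x)) x$tm_C else as.numeric(x)
  })
  if (length(vals) < 2L) stopf("need >= 2 labels to compare")
  if (any(vapply(vals, length, 1L) < 2L))
    stopf("each label needs >= 2 Tm results")
  labs <- names(vals)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    p <- compare_groups(a, b, test = "student_t")$p_value
    data.frame(label_a = pr[1], label_b = pr[2], n_a = length(a),
               n_b = length(b), delta_tm_C = mean(a) - mean(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
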