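# Growth-curve and cell-cycle kinetics: population doubling time from
# exponential counts, S-phase substage fractions from a manual census, and
# substage durations = doubling time x fraction.

#' Population doubling time from a growth series
#'
#' The doubling rate is `log2(n_x / n_0) / t` (doublings per hour); its
#' reciprocal is the doubling time in hours. `"endpoint"` uses the last
#' timepoint only; `"regression"` (default, robust to count noise) takes
#' `1 / slope` of the OLS fit of `log2(count)` against time.
#'
#' @param series Data frame with `time_h` (ascending, first = 0) and `count`
#'   (> 0).
#' @param method `"regression"` or `"endpoint"`.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(series, method = c("regression", "endpoint")) {
  method <- match.arg(method)
  stopifnot(all(c("time_h", "count") %in% names(series)))
  if (nrow(series) < 2L) stopf("need >= 2 timepoints")
  if (any(series$count <= 0)) stopf("counts must be > 0")
  if (series$time_h[1] != 0) stopf("series must start at t = 0 (seeding)")
  if (method == "endpoint") {
    n <- nrow(series)
    n0 <- series$count[1]; nx <- series$count[n]; t <- series$time_h[n]
    if (nx <= n0) stopf("no net growth (n_x <= n_0); doubling time undefined")
    rate <- log2(nx / n0) / t
    return(1 / rate)
  }
  fit <- stats::lm(log2(count) ~ time_h, data = series)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stopf("no net growth (non-positive regression slope)")
  1 / slope
}

#' Fractions of cells per cell-cycle / S-phase substage
#'
#' @param census Named numeric vector or data frame (`category`, `count`) of
#'   cells per category; S-phase substages are every category not named in
#'   `non_s_categories`.
#' @param non_s_categories Categories outside S phase.
#' @return List with `fractions` (data frame: `category`, `count`,
#'   `fraction`) and `s_phase_fraction`.
#' @export
substage_fractions <- function(census,
                               non_s_categories = c("non-S", "mitosis")) {
  if (is.data.frame(census)) {
    counts <- stats::setNames(census$count, census$category)
  } else counts <- census
  if (any(counts < 0)) stopf("counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stopf("total cell count must be > 0")
  fr <- counts / total
  list(fractions = data.frame(category = names(counts),
                              count = as.numeric(counts),
                              fraction = as.numeric(fr),
                              stringsAsFactors = FALSE),
       s_phase_fraction = sum(fr[!names(fr) %in% non_s_categories]))
}

#' Duration of a cell-cycle phase or S-phase substage
#'
#' `duration = doubling time x fraction of cells in the phase`; for an
#' asynchronous exponentially growing population the time spent in a phase is
#' proportional to its occupancy. Durations over all categories therefore
#' sum exactly to the doubling time.
#'
#' @param doubling_h Doubling time in hours (> 0).
#' @param fraction Fraction(s) of cells in the phase, each in `[0, 1]`.
#' @return Duration(s) in hours.
#' @export
substage_duration <- function(doubling_h, fraction) {
  assert_scalar_num(doubling_h, "doubling_h", lower = 0, strict = TRUE)
  if (any(fraction < 0 | fraction > 1)) stopf("fractions must be in [0, 1]")
  doubling_h * fraction
}

#' Full cell-cycle kinetics table
#'
#' Convenience wrapper: doubling time from the growth series, fractions from
#' the census, and per-category durations.
#'
#' @param series Growth series, see [doubling_time()].
#' @param census Substage census, see [substage_fractions()].
#' @param method Doubling-time method.
#' @return List: `doubling_h`, `s_phase_fraction`, `s_phase_h`, and
#'   `kinetics` (category, count, fraction, duration_h).
#' @export
cellcycle_kinetics <- function(series, census, method = "regression") {
  dt <- doubling_time(series, method)
  fr <- substage_fractions(census)
  kin <- fr$fractions
  kin$duration_h <- substage_duration(dt, kin$fraction)
  list(doubling_h = dt, s_phase_fraction = fr$s_phase_fraction,
       s_phase_h = dt * fr$s_phase_fraction, kinetics = kin)
}
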