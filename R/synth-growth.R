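# Synthetic exponential growth counts with multiplicative lognormal noise.

#' Simulate cell-growth counts
#'
#' `n(t) = n0 * 2^(t / doubling_h)` with multiplicative lognormal noise whose
#' coefficient of variation is `cv_noise` (the lognormal is mean-1 so noisy
#' counts are unbiased).
#'
#' @param n0 Seeded cell number (> 0).
#' @param doubling_h True doubling time in hours (> 0).
#' @param sample_times_h Ascending sampling times, first = 0.
#' @param cv_noise Coefficient of variation of the count noise (>= 0).
#' @param seed Integer seed.
#' @return List with `series` (data frame: `time_h`, `count`) and `truth`
#'   (`sim_truth` with `true_doubling_h`, `n0`, `cv_noise`).
#' @export
make_growth_counts <- function(n0 = 2e5, doubling_h = 14,
                               sample_times_h = c(0, 24, 48, 72, 96),
                               cv_noise = 0.05, seed = 1) {
  assert_scalar_num(n0, "n0", lower = 0, strict = TRUE)
  assert_scalar_num(doubling_h, "doubling_h", lower = 0, strict = TRUE)
  assert_scalar_num(cv_noise, "cv_noise", lower = 0)
  if (is.unsorted(sample_times_h, strictly = TRUE) || sample_times_h[1] != 0)
    stopf("sample_times_h must be strictly ascending starting at 0")
  set.seed(seed)
  mu <- n0 * 2^(sample_times_h / doubling_h)
  counts <- if (cv_noise > 0) {
    sdlog <- sqrt(log(1 + cv_noise^2))
    mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
  } else mu
  list(series = data.frame(time_h = sample_times_h, count = counts),
       truth = sim_truth("make_growth_counts", seed,
                         list(true_doubling_h = doubling_h, n0 = n0,
                              cv_noise = cv_noise)))
}
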