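#' Modification labels recognised by the melting simulator
#'
#' The closed vocabulary of cytosine species: unmodified cytosine and its
#' methylated/oxidised derivatives.
#'
#' @return Character vector of valid labels.
#' @export
modification_labels <- function() c("C", "5mC", "5hmC", "5fC", "5caC")

#' Default two-state melting configuration
#'
#' Nominal melting temperatures for amplicons carrying each cytosine species.
#' The base Tm and the per-modification shifts are implementation defaults
#' chosen to reproduce the qualitative stability ordering
#' Tm(5fC) < Tm(5hmC) ~ Tm(5caC) < Tm(C) < Tm(5mC); they are not measured
#' values and can be overridden via `tm_config`.
#'
#' @param tm_base Tm of the unmodified-cytosine duplex, degrees C.
#' @param delta_tm Named numeric vector of Tm shifts per label, degrees C.
#' @param width Transition width of the two-state logistic, degrees C.
#' @return List with `tm` (named vector, one Tm per label) and `width`.
#' @export
default_tm_config <- function(tm_base = 78.0,
                              delta_tm = c(C = 0, `5mC` = 1.2, `5hmC` = -0.8,
                                           `5caC` = -0.9, `5fC` = -2.0),
                              width = 1.0) {
  stopifnot(all(names(delta_tm) %in% modification_labels()))
  list(tm = tm_base + delta_tm[modification_labels()[modification_labels() %in% names(delta_tm)]],
       width = width)
}

#' Simulate SYBR-green melting curves for modified templates
#'
#' Generates two-state melting traces on the instrument ramp (50--90 degrees C
#' in 0.1 degree steps): `F(T) = b0 + b1*T + a * theta(T) + noise`, with
#' `theta(T) = 1 / (1 + exp((T - Tm) / w))`, so fluorescence is high while the
#' duplex is intact and decays through the transition. Each label's Tm comes
#' from `tm_config`.
#'
#' @param labels Character vector of modification labels (see
#'   [modification_labels()]).
#' @param n_replicates Technical replicates per label (>= 1).
#' @param noise_sd SD of additive Gaussian fluorescence noise (>= 0).
#' @param seed Integer seed; fully determines the output.
#' @param tm_config Melting configuration, see [default_tm_config()].
#' @param temp_range Ramp limits in degrees C.
#' @param temp_step Ramp step in degrees C (instrument default 0.1).
#' @param amplitude Transition amplitude `a` in fluorescence units.
#' @param baseline Numeric `c(b0, b1)` of the linear baseline.
#' @return List with `curves` (long data.frame: curve_id, label, replicate_id,
#'   temp_C, fluor) and `truth` (a `sim_truth` recording each label's Tm,
#'   width and noise level).
#' @export
make_melt_curves <- function(labels, n_replicates = 4, noise_sd = 0.01,
                             seed = 1, tm_config = default_tm_config(),
                             temp_range = c(50, 90), temp_step = 0.1,
                             amplitude = 1, baseline = c(0.05, -5e-4)) {
  if (length(labels) < 1L) stopf("at least one label required")
  bad <- setdiff(labels, modification_labels())
  if (length(bad))
    stopf("unknown modification label(s): %s", paste(bad, collapse = ", "))
  bad_tm <- setdiff(labels, names(tm_config$tm))
  if (length(bad_tm))
    stopf("tm_config has no Tm for label(s): %s", paste(bad_tm, collapse = ", "))
  assert_scalar_num(n_replicates, "n_replicates", lower = 1)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)

  set.seed(seed)
  temps <- seq(temp_range[1], temp_range[2], by = temp_step)
  out <- vector("list", length(labels) * n_replicates)
  k <- 0L
  for (lab in labels) {
    tm <- unname(tm_config$tm[lab])
    theta <- 1 / (1 + exp((temps - tm) / tm_config$width))
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      fl <- baseline[1] + baseline[2] * temps + amplitude * theta +
        stats::rnorm(length(temps), 0, noise_sd)
      out[[k]] <- data.frame(
        curve_id = sprintf("%s_rep%d", lab, r), label = lab,
        replicate_id = sprintf("rep%d", r), temp_C = temps, fluor = fl,
        stringsAsFactors = FALSE)
    }
  }
  truth <- sim_truth("make_melt_curves", seed, list(
    true_tm = tm_config$tm[labels], width = tm_config$width,
    amplitude = amplitude, baseline = baseline, noise_sd = noise_sd,
    temp_step = temp_step))
  list(curves = do.call(rbind, out), truth = truth)
}
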