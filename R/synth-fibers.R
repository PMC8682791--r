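# Synthetic dual-pulse fiber tracks with a known fork-speed distribution.

# truncated normal on (0, Inf) by rejection; mean/sd are the parent normal's
rtruncnorm_pos <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Simulate a set of combed DNA fiber tracks
#'
#' Progressing tracks draw a fork speed `v` from a truncated normal (v > 0)
#' and get IdU and CldU segment lengths `v * pulse_min / conversion` um (the
#' combing calibration maps 1 um to `conversion` kb). Non-progressing
#' classes carry only the corresponding segment(s): `cldu_only`, `idu_only`,
#' or `other` (reversed CldU->IdU order).
#'
#' @param n_tracks Number of tracks.
#' @param speed_mean_kb_per_min,speed_sd Parent normal parameters of the true
#'   fork-speed distribution (kb/min).
#' @param pulse_min Labelling pulse duration per analog, minutes.
#' @param class_probs Named probabilities over
#'   `{progressing, cldu_only, idu_only, other}`, summing to 1.
#' @param conversion_kb_per_um Combing calibration, kb per um.
#' @param seed Integer seed.
#' @return List with `tracks` (data frame: `track_id`, `order`,
#'   `idu_len_um`, `cldu_len_um`, `ssdna_ok`) and `truth` (`sim_truth` with
#'   per-track class and true speed).
#' @export
make_fiber_set <- function(n_tracks, speed_mean_kb_per_min = 1.5,
                           speed_sd = 0.3, pulse_min = 15,
                           class_probs = c(progressing = 0.7, cldu_only = 0.1,
                                           idu_only = 0.1, other = 0.1),
                           conversion_kb_per_um = 2, seed = 1) {
  req <- c("progressing", "cldu_only", "idu_only", "other")
  if (!all(req %in% names(class_probs)) || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8)
    stopf("class_probs must be non-negative over {%s} and sum to 1",
          paste(req, collapse = ", "))
  assert_scalar_num(pulse_min, "pulse_min", lower = 0, strict = TRUE)
  set.seed(seed)
  cls <- sample(req, n_tracks, replace = TRUE, prob = class_probs[req])
  v <- rtruncnorm_pos(n_tracks, speed_mean_kb_per_min, speed_sd)
  len <- v * pulse_min / conversion_kb_per_um
  ord <- character(n_tracks)
  idu <- numeric(n_tracks); cldu <- numeric(n_tracks)
  for (i in seq_len(n_tracks)) {
    switch(cls[i],
      progressing = { ord[i] <- "IdU>CldU"; idu[i] <- len[i]; cldu[i] <- len[i] },
      cldu_only   = { ord[i] <- "CldU"; cldu[i] <- len[i] },
      idu_only    = { ord[i] <- "IdU"; idu[i] <- len[i] },
      other       = { ord[i] <- "CldU>IdU"; idu[i] <- len[i]; cldu[i] <- len[i] })
  }
  tracks <- data.frame(track_id = sprintf("trk%04d", seq_len(n_tracks)),
                       order = ord, idu_len_um = idu, cldu_len_um = cldu,
                       ssdna_ok = TRUE, stringsAsFactors = FALSE)
  truth <- sim_truth("make_fiber_set", seed, list(
    class = cls, true_speed_kb_per_min = v,
    speed_mean = speed_mean_kb_per_min, speed_sd = speed_sd,
    pulse_min = pulse_min, conversion_kb_per_um = conversion_kb_per_um))
  list(tracks = tracks, truth = truth)
}
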