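# Synthetic RPA time-lapse stacks: a disk nucleus with Gaussian replication
# foci whose focal signal grows linearly in time under polymerase inhibition
# (APH) and stays flat under vehicle (DMSO). The focal pattern G(x) is fixed
# over time, so pixel values are B + s(t) * G(x) and the nuclear cV has the
# closed form cv(t) = s(t) * sd(G) / (B + s(t) * mean(G)); the truth record
# carries mean(G) and sd(G) for that oracle.

#' Simulate an RPA accumulation time-lapse
#'
#' One nucleus (disk mask) with `n_foci` Gaussian replication foci
#' (sigma 2 px). Under `"APH"` the focal amplitude follows
#' `I(t) = I0 * (1 + r * t)` with `r = accumulation_rate`; under `"DMSO"` it
#' stays at `I0`. A constant diffuse nuclear background and Gaussian read
#' noise complete the frame model.
#'
#' @param treatment `"APH"` or `"DMSO"`.
#' @param accumulation_rate Per-minute fractional accumulation rate `r`
#'   (>= 0).
#' @param frame_times_min Ascending frame times in minutes; the first must be
#'   0 (the pretreatment frame).
#' @param seed Integer seed.
#' @param size Frame edge length in pixels.
#' @param nucleus_radius_px Radius of the disk nucleus.
#' @param n_foci Number of replication foci.
#' @param background Diffuse nuclear intensity `B` (a.u.).
#' @param focal_amplitude Pretreatment focal amplitude `I0` (a.u.).
#' @param noise_sd SD of Gaussian read noise (a.u.).
#' @return List with `stack` (list: `frames`, `times_min`, `treatment`,
#'   `mask`) and `truth` (`sim_truth` with `rate`, `background`, `i0`,
#'   `g_mean`, `g_sd`).
#' @export
make_rpa_timelapse <- function(treatment = c("APH", "DMSO"),
                               accumulation_rate = 0.05,
                               frame_times_min = c(0, 5, 10, 15, 20, 25, 30),
                               seed = 1, size = 128, nucleus_radius_px = 48,
                               n_foci = 25, background = 100,
                               focal_amplitude = 100, noise_sd = 2) {
  treatment <- match.arg(treatment)
  if (accumulation_rate < 0) stopf("accumulation rate must be >= 0")
  if (is.unsorted(frame_times_min, strictly = TRUE))
    stopf("frame_times_min must be strictly ascending")
  if (frame_times_min[1] != 0)
    stopf("first frame time must be 0 (pretreatment)")
  set.seed(seed)

  ctr <- size / 2
  xg <- matrix(rep(seq_len(size), size), size)
  yg <- t(xg)
  mask <- (xg - ctr)^2 + (yg - ctr)^2 <= nucleus_radius_px^2

  # fixed focal pattern G(x): unit-amplitude Gaussians at random positions
  g <- matrix(0, size, size)
  ang <- stats::runif(n_foci, 0, 2 * pi)
  rad <- nucleus_radius_px * sqrt(stats::runif(n_foci)) * 0.9
  fx <- ctr + rad * cos(ang)
  fy <- ctr + rad * sin(ang)
  for (k in seq_len(n_foci))
    g <- g + exp(-((xg - fx[k])^2 + (yg - fy[k])^2) / (2 * 2^2))
  g[!mask] <- 0

  gm <- g[mask]
  frames <- lapply(frame_times_min, function(t) {
    s <- if (treatment == "APH") focal_amplitude * (1 + accumulation_rate * t)
         else focal_amplitude
    fr <- matrix(0, size, size)
    fr[mask] <- background + s * gm
    if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
    fr
  })
  stack <- list(frames = frames, times_min = frame_times_min,
                treatment = treatment, mask = mask)
  truth <- sim_truth("make_rpa_timelapse", seed, list(
    rate = if (treatment == "APH") accumulation_rate else 0,
    background = background, i0 = focal_amplitude,
    g_mean = mean(gm), g_sd = pop_sd(gm), noise_sd = noise_sd))
  list(stack = stack, truth = truth)
}

#' Closed-form normalized cV of the two-component focal model
#'
#' For pixel values `B + s(t) * G(x)` with `s(t) = I0 * (1 + r * t)` the
#' nuclear coefficient of variation is
#' `cv(t) = s(t) * sd(G) / (B + s(t) * mean(G))`; this returns
#' `cv(t) / cv(0)` at the requested times. Used as the independent oracle for
#' slope-recovery tests.
#'
#' @param times_min Times in minutes.
#' @param rate Accumulation rate `r` per minute.
#' @param background,i0 Model intensities `B` and `I0`.
#' @param g_mean,g_sd Mean and population SD of the focal pattern over the
#'   nuclear mask.
#' @return Numeric vector of normalized cV values.
#' @export
expected_cv_norm <- function(times_min, rate, background, i0, g_mean, g_sd) {
  s <- i0 * (1 + rate * times_min)
  cv <- s * g_sd / (background + s * g_mean)
  cv / cv[1]
}
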