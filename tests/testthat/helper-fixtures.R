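# shared fixtures built in code

# a field with one centered disk nucleus of the given radius (um)
disk_field <- function(radius_um, pixel_size_um = 0.2, size_px = 256,
                       level = 500, background = 10, extra = list()) {
  r_px <- radius_um / pixel_size_um
  x <- matrix(rep(seq_len(size_px), size_px), size_px)
  y <- t(x)
  sel <- (x - size_px / 2)^2 + (y - size_px / 2)^2 <= r_px^2
  dapi <- matrix(background, size_px, size_px)
  dapi[sel] <- level
  ch <- c(list(DAPI = dapi), extra)
  list(field = image_field(ch, pixel_size_um), mask = sel)
}

# noiseless single-label melt curve plus its closed-form duplex fraction
noiseless_melt <- function(label = "C", seed = 1) {
  sim <- make_melt_curves(label, n_replicates = 1, noise_sd = 0, seed = seed)
  cv <- sim$curves
  tm <- unname(sim$truth$params$true_tm[label])
  theta <- 1 / (1 + exp((cv$temp_C - tm) / sim$truth$params$width))
  list(curve = cv, theta = theta, tm = tm)
}
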