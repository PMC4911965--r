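# Independent oracles and small shared fixtures. Everything here is
# deliberately brute-force and kept independent of the implementation paths
# it checks.

# Dense supersampled rasterisation of a centred disc: every pixel's coverage
# fraction estimated from an ss x ss sub-pixel grid.
dense_disc_oracle <- function(diameter_mm, contrast_hu, pixel_pitch, roi_side,
                              ss = 100L) {
  r <- diameter_mm / 2 / pixel_pitch
  ctr <- (roi_side + 1) / 2
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  out <- matrix(0, roi_side, roi_side)
  for (i in seq_len(roi_side)) {
    px2 <- ((i - ctr) + off)^2
    for (j in seq_len(roi_side)) {
      py2 <- ((j - ctr) + off)^2
      out[i, j] <- mean(outer(px2, py2, `+`) <= r * r)
    }
  }
  out * contrast_hu
}

# Analytic peak frequency of a difference-of-Gaussians radial profile with
# narrow scale sigma and width ratio W (from setting the derivative to zero).
dog_peak_analytic <- function(sigma, W) {
  sigma * W * sqrt(4 * log(W) / (W^2 - 1))
}

# Monte-Carlo M-AFC percent correct for Gaussian scores, chunked to bound
# memory.
mc_mafc_pc <- function(dprime, m, n, seed, chunk = 1e6L) {
  set.seed(seed)
  hits <- 0
  left <- n
  while (left > 0) {
    k <- min(chunk, left)
    s <- rnorm(k, mean = dprime)
    mx <- rnorm(k)
    for (i in seq_len(m - 2L)) mx <- pmax(mx, rnorm(k))
    hits <- hits + sum(s > mx)
    left <- left - k
  }
  100 * hits / n
}

# Small shared fixtures (built once per test file). On a 21-pixel ROI the
# default channel set's lowest bands fall below the grid's lowest nonzero
# frequency and carry no energy, so the small-ROI bank uses fewer channels
# with the band edges shifted up.
tiny_side <- 21L
tiny_nch <- 8L
tiny_params <- channel_params(n_channels = tiny_nch, sigma0 = 0.01)
tiny_bank <- build_channel_bank(tiny_side, params = tiny_params)

tiny_dataset <- function(contrast = 15, sigma = 5, n_signal = 30L,
                         n_noise = 120L, seed = 11L, diameter = 4) {
  generate_category_dataset(category(15, 1L, contrast, diameter),
                            noise_model("white", sigma),
                            n_signal = n_signal, n_noise = n_noise,
                            seed = seed, roi_side = tiny_side)
}
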