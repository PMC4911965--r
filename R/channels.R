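# Dense difference-of-Gaussian (DDoG) channel bank. Each channel is the
# difference of two Gaussians in radial spatial frequency; the bank projects
# a flattened ROI onto a small channel-output vector.

#' DDoG channel parameters
#'
#' The radial profile of channel j is
#' `U_j(rho) = exp(-0.5 (rho / (W sigma_j))^2) - exp(-0.5 (rho / sigma_j)^2)`
#' with `sigma_j = sigma0 * alpha^j`, j = 1..n_channels, and rho the radial
#' spatial frequency in cycles/pixel. Defaults are the standard dense DoG
#' set: 10 channels, W = 1.67, sigma0 = 0.005, alpha = 1.4.
#'
#' @param n_channels Number of channels (>= 1).
#' @param bandwidth_W Ratio of the two Gaussian widths (> 1).
#' @param sigma0 Base radial-frequency scale in cycles/pixel (> 0).
#' @param alpha Geometric ratio between successive channel scales (> 1).
#'
#' @return A list of class `channel_params`.
#' @export
channel_params <- function(n_channels = 10L, bandwidth_W = 1.67,
                           sigma0 = 0.005, alpha = 1.4) {
  n_channels <- assert_count(n_channels, "n_channels", min = 1L)
  if (bandwidth_W <= 1) abort("`bandwidth_W` must be > 1 (wider minus narrower Gaussian)")
  assert_positive(sigma0, "sigma0")
  if (alpha <= 1) abort("`alpha` must be > 1")
  structure(list(n_channels = n_channels, bandwidth_W = as.double(bandwidth_W),
                 sigma0 = as.double(sigma0), alpha = as.double(alpha)),
            class = "channel_params")
}

#' DDoG radial frequency response
#'
#' Evaluates the radial profile of channel `j` at frequency `rho`
#' (cycles/pixel). The response is 0 at rho = 0, rises to a single peak and
#' decays back to 0; it is non-negative for all rho when `bandwidth_W > 1`.
#'
#' @param rho Radial spatial frequency in cycles/pixel (vectorised, >= 0).
#' @param j Channel index, 1-based.
#' @param params A [channel_params()].
#'
#' @return Numeric vector of responses, same length as `rho`.
#' @export
#' @examples
#' ddog_profile(seq(0, 0.5, by = 0.01), j = 5, channel_params())
ddog_profile <- function(rho, j, params = channel_params()) {
  stopifnot(inherits(params, "channel_params"))
  j <- assert_count(j, "j")
  if (j > params$n_channels) {
    abort(sprintf("channel index %d out of range 1..%d", j, params$n_channels))
  }
  if (any(rho < 0)) abort("`rho` must be >= 0")
  sig_j <- params$sigma0 * params$alpha^j
  exp(-0.5 * (rho / (params$bandwidth_W * sig_j))^2) - exp(-0.5 * (rho / sig_j)^2)
}

#' Build the spatial channel bank
#'
#' Samples each channel's radial profile on the 2-D discrete-frequency grid
#' of a `roi_side` x `roi_side` transform (rho = sqrt(fx^2 + fy^2) in
#' cycles/pixel), inverse-transforms to a real spatial template centred on
#' the ROI centre pixel, and stores the flattened template as one column of
#' the channel matrix U.
#'
#' @param roi_side ROI side length in pixels (odd, >= 3).
#' @param pixel_pitch Pixel size in mm; carried as metadata only — channel
#'   frequencies are in cycles/pixel, so the observer is pitch-invariant.
#' @param params A [channel_params()].
#'
#' @return A list of class `channel_bank` with elements `U`
#'   (`roi_side^2` x `n_channels` matrix), `params`, `roi_side`,
#'   `pixel_pitch`.
#' @export
#' @examples
#' bank <- build_channel_bank(41)
#' dim(bank$U)  # 1681 x 10
build_channel_bank <- function(roi_side = 41L, pixel_pitch = 0.59,
                               params = channel_params()) {
  stopifnot(inherits(params, "channel_params"))
  roi_side <- assert_count(roi_side, "roi_side", min = 3L)
  if (roi_side %% 2L == 0L) abort("`roi_side` must be odd so the templates have a centre pixel")
  f <- fft_freqs(roi_side)
  rho <- sqrt(outer(f^2, f^2, `+`))
  ctr <- (roi_side + 1L) %/% 2L
  shift <- ((seq_len(roi_side) - ctr) %% roi_side) + 1L
  U <- matrix(0, roi_side^2, params$n_channels)
  for (j in seq_len(params$n_channels)) {
    freq <- ddog_profile(rho, j, params)
    tmpl <- stats::fft(freq, inverse = TRUE) / roi_side^2
    # the sampled profile is even on the DFT grid, so tmpl is real up to
    # rounding; realise it and recentre on the centre pixel
    tmpl <- Re(tmpl)[shift, shift]
    U[, j] <- flatten_roi(tmpl)
  }
  structure(list(U = U, params = params, roi_side = roi_side,
                 pixel_pitch = as.double(pixel_pitch)),
            class = "channel_bank")
}

#' @export
print.channel_bank <- function(x, ...) {
  cat(sprintf("<channel_bank: %d DDoG channels on %dx%d ROIs (W=%g, sigma0=%g, alpha=%g)>\n",
              x$params$n_channels, x$roi_side, x$roi_side,
              x$params$bandwidth_W, x$params$sigma0, x$params$alpha))
  invisible(x)
}

#' Project an ROI onto the channel bank
#'
#' Computes the channel-output vector `t(U) %*% g` for a flattened ROI `g`.
#' The operation is linear in the ROI, and because every channel has zero
#' mean it is invariant to a constant HU offset.
#'
#' @param roi A `roi_side` x `roi_side` matrix (or a side^2 vector).
#' @param bank A [build_channel_bank()] result.
#'
#' @return Numeric vector of length `n_channels`.
#' @export
apply_channels <- function(roi, bank) {
  stopifnot(inherits(bank, "channel_bank"))
  if (is.matrix(roi)) {
    if (nrow(roi) != bank$roi_side || ncol(roi) != bank$roi_side) {
      abort(sprintf("ROI is %dx%d but the bank was built for %dx%d",
                    nrow(roi), ncol(roi), bank$roi_side, bank$roi_side))
    }
    roi <- flatten_roi(roi)
  }
  if (length(roi) != nrow(bank$U)) {
    abort(sprintf("flattened ROI has length %d but the bank expects %d",
                  length(roi), nrow(bank$U)))
  }
  drop(crossprod(bank$U, roi))
}

# Channel outputs for a whole stack at once: returns n_channels x n matrix.
channelize_stack <- function(rois, bank) {
  g <- roi_stack_matrix(rois, side = bank$roi_side)
  crossprod(bank$U, g)
}
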