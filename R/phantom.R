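# Synthetic phantom module: noise-free disc targets, seeded noise fields and
# complete per-category ROI datasets with the statistical structure the
# observer analysis assumes (signal known exactly, location known, stationary
# noise).

#' Acquisition category
#'
#' One cell of the factorial study design: a nominal dose level (CTDI_vol),
#' an iterative-reconstruction strength label, a target contrast and a target
#' diameter.
#'
#' @param dose_mGy Nominal CTDI_vol in mGy; must be positive.
#' @param recon_strength Integer reconstruction-strength label in 1..5.
#' @param contrast_hu Target contrast in HU (>= 0).
#' @param diameter_mm Target diameter in mm (> 0).
#'
#' @return A list of class `cho_category`.
#' @export
#' @examples
#' category(dose_mGy = 3.5, recon_strength = 1, contrast_hu = 10, diameter_mm = 6)
category <- function(dose_mGy, recon_strength = 1L, contrast_hu = 10, diameter_mm = 6) {
  assert_positive(dose_mGy, "dose_mGy")
  recon_strength <- assert_count(recon_strength, "recon_strength", min = 1L)
  if (recon_strength > 5L) abort("`recon_strength` must be in 1..5")
  if (!is.numeric(contrast_hu) || contrast_hu < 0) abort("`contrast_hu` must be >= 0")
  assert_positive(diameter_mm, "diameter_mm")
  structure(list(dose_mGy = as.double(dose_mGy),
                 recon_strength = recon_strength,
                 contrast_hu = as.double(contrast_hu),
                 diameter_mm = as.double(diameter_mm)),
            class = "cho_category")
}

#' @export
format.cho_category <- function(x, ...) {
  sprintf("<category %g mGy | strength %d | %g HU | %g mm>",
          x$dose_mGy, x$recon_strength, x$contrast_hu, x$diameter_mm)
}

#' @export
print.cho_category <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Noise model for synthetic ROIs
#'
#' Describes the surrogate noise added to synthetic ROIs. `"white"` is
#' independent Gaussian noise per pixel; `"nps_shaped"` filters a white field
#' in the frequency domain by the square root of a radial power spectrum
#' proportional to `rho^nps_exponent * exp(-rho)` (rho in cycles/pixel), then
#' rescales so the expected pixel standard deviation equals `sigma_hu`.
#'
#' @param kind `"white"` or `"nps_shaped"`.
#' @param sigma_hu Noise standard deviation in HU (>= 0).
#' @param nps_exponent Spectral shaping exponent; used only for
#'   `"nps_shaped"`.
#'
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("white", "nps_shaped"), sigma_hu = 10, nps_exponent = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma_hu) || length(sigma_hu) != 1L || sigma_hu < 0 || !is.finite(sigma_hu)) {
    abort("`sigma_hu` must be a single number >= 0")
  }
  if (kind == "nps_shaped") assert_positive(nps_exponent, "nps_exponent")
  structure(list(kind = kind, sigma_hu = as.double(sigma_hu),
                 nps_exponent = as.double(nps_exponent)),
            class = "noise_model")
}

#' Noise-free disc signal profile
#'
#' Renders the low-contrast target as a centred anti-aliased disc on a square
#' ROI: interior pixels take the plateau value `contrast_hu`, the far field is
#' 0, and boundary pixels take fractional values by sub-pixel area sampling
#' (16 x 16 supersampling of partially covered pixels).
#'
#' @param diameter_mm Disc diameter in mm.
#' @param contrast_hu Plateau amplitude in HU.
#' @param pixel_pitch Pixel size in mm (default 0.59).
#' @param roi_side ROI side length in pixels; must be odd so a centre pixel
#'   exists (default 41).
#'
#' @return A `roi_side` x `roi_side` numeric matrix of HU values with
#'   attribute `pixel_pitch`.
#' @export
#' @examples
#' prof <- make_signal_profile(8, 20)
#' prof[21, 21]  # plateau
make_signal_profile <- function(diameter_mm, contrast_hu, pixel_pitch = 0.59,
                                roi_side = 41L) {
  assert_positive(diameter_mm, "diameter_mm")
  assert_positive(pixel_pitch, "pixel_pitch")
  roi_side <- assert_count(roi_side, "roi_side", min = 3L)
  if (roi_side %% 2L == 0L) abort("`roi_side` must be odd so a centre pixel exists")
  if (diameter_mm / pixel_pitch >= roi_side) {
    abort(sprintf("disc of %g mm (%.1f px) does not fit in a %d px ROI",
                  diameter_mm, diameter_mm / pixel_pitch, roi_side))
  }
  r <- diameter_mm / 2 / pixel_pitch          # radius in pixel units
  ctr <- (roi_side + 1L) / 2
  d1 <- abs(seq_len(roi_side) - ctr)          # per-axis centre distance
  dx <- matrix(d1, roi_side, roi_side)
  dy <- t(dx)
  # conservative classification by nearest/farthest point of the unit pixel
  near <- sqrt(pmax(dx - 0.5, 0)^2 + pmax(dy - 0.5, 0)^2)
  far <- sqrt((dx + 0.5)^2 + (dy + 0.5)^2)
  cov <- matrix(0, roi_side, roi_side)
  cov[far <= r] <- 1
  edge <- which(near < r & far > r)
  if (length(edge)) {
    ss <- 16L
    off <- (seq_len(ss) - 0.5) / ss - 0.5     # sub-pixel centre offsets
    gx <- rep(off, times = ss)
    gy <- rep(off, each = ss)
    for (idx in edge) {
      i <- (idx - 1L) %% roi_side + 1L
      j <- (idx - 1L) %/% roi_side + 1L
      px <- (i - ctr) + gx
      py <- (j - ctr) + gy
      cov[idx] <- mean(px * px + py * py <= r * r)
    }
  }
  out <- cov * contrast_hu
  attr(out, "pixel_pitch") <- pixel_pitch
  out
}

#' Single seeded noise ROI
#'
#' Draws one zero-mean noise field under a [noise_model()]. White noise is
#' i.i.d. Gaussian per pixel. NPS-shaped noise filters a white field in the
#' frequency domain by the square root of the radial power spectrum
#' `rho^nps_exponent * exp(-rho)` (DC term zero), normalised so the expected
#' per-pixel standard deviation equals `sigma_hu`.
#'
#' @param model A [noise_model()].
#' @param roi_side ROI side length in pixels.
#' @param seed Integer seed; the same (model, side, seed) always yields a
#'   bit-identical ROI.
#'
#' @return A `roi_side` x `roi_side` numeric matrix.
#' @export
generate_noise_roi <- function(model, roi_side = 41L, seed = 1L) {
  stopifnot(inherits(model, "noise_model"))
  roi_side <- assert_count(roi_side, "roi_side", min = 3L)
  seed <- assert_count(seed, "seed", min = 0L)
  if (model$sigma_hu == 0) return(matrix(0, roi_side, roi_side))
  set.seed(seed)
  w <- matrix(rnorm(roi_side^2), roi_side, roi_side)
  if (model$kind == "white") {
    return(model$sigma_hu * w)
  }
  h <- nps_filter(roi_side, model$nps_exponent)
  x <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / roi_side^2
  model$sigma_hu * x
}

# Frequency-domain amplitude filter for nps_shaped noise, normalised so that
# filtering unit-variance white noise yields unit per-pixel variance.
nps_filter <- function(roi_side, nps_exponent) {
  f <- fft_freqs(roi_side)
  rho <- sqrt(outer(f^2, f^2, `+`))
  h <- sqrt(rho^nps_exponent * exp(-rho))
  h[1L, 1L] <- 0
  h / sqrt(mean(h^2))
}

#' Quantum-noise scaling of sigma with dose
#'
#' Maps a nominal CTDI_vol to a noise magnitude by inverse-square-root
#' scaling from a reference point:
#' `sigma = reference_sigma_hu * sqrt(reference_dose_mGy / dose_mGy)`.
#'
#' @param dose_mGy Dose at which the noise level is wanted (mGy).
#' @param reference_sigma_hu Noise SD in HU measured/assumed at the reference
#'   dose.
#' @param reference_dose_mGy Reference dose in mGy.
#'
#' @return Noise standard deviation in HU.
#' @export
#' @examples
#' dose_to_sigma(c(1, 3.5, 8, 15), reference_sigma_hu = 10, reference_dose_mGy = 15)
dose_to_sigma <- function(dose_mGy, reference_sigma_hu, reference_dose_mGy) {
  if (any(!is.finite(dose_mGy)) || any(dose_mGy <= 0)) abort("`dose_mGy` must be positive")
  assert_positive(reference_sigma_hu, "reference_sigma_hu")
  assert_positive(reference_dose_mGy, "reference_dose_mGy")
  reference_sigma_hu * sqrt(reference_dose_mGy / dose_mGy)
}

#' Generate a complete per-category ROI dataset
#'
#' Emulates one acquisition category of the phantom study: `n_signal`
#' signal-present ROIs (noise-free disc profile plus independent noise draws)
#' and `n_noise` signal-absent ROIs (noise only). Every draw derives from the
#' master `seed` through per-ROI counter-based substreams, so the dataset is
#' bit-reproducible and insertion order never shifts draws.
#'
#' @param category A [category()].
#' @param model A [noise_model()]; its `sigma_hu` is used as given (see
#'   [dose_to_sigma()] to derive it from dose).
#' @param n_signal Number of signal-present ROIs (default 100).
#' @param n_noise Number of signal-absent ROIs (default 1000; at least 4 so a
#'   4-AFC trial can draw three distinct noise alternatives).
#' @param seed Master integer seed for the dataset.
#' @param roi_side,pixel_pitch ROI geometry (defaults 41 px, 0.59 mm).
#'
#' @return A list of class `roi_dataset` with elements `category`, `model`,
#'   `signal` (side x side x n_signal array), `noise` (side x side x n_noise
#'   array), `truth` (noise-free profile), `pixel_pitch`, `seed`.
#' @export
generate_category_dataset <- function(category, model, n_signal = 100L,
                                      n_noise = 1000L, seed = 1L,
                                      roi_side = 41L, pixel_pitch = 0.59) {
  stopifnot(inherits(category, "cho_category"), inherits(model, "noise_model"))
  n_signal <- assert_count(n_signal, "n_signal", min = 1L)
  if (n_noise < 4L) {
    abort("`n_noise` must be at least 4: a 4-AFC trial needs three distinct signal-absent ROIs")
  }
  n_noise <- assert_count(n_noise, "n_noise", min = 4L)
  seed <- assert_count(seed, "seed", min = 0L)
  truth <- make_signal_profile(category$diameter_mm, category$contrast_hu,
                               pixel_pitch = pixel_pitch, roi_side = roi_side)
  attr(truth, "pixel_pitch") <- NULL
  sig <- array(0, dim = c(roi_side, roi_side, n_signal))
  for (k in seq_len(n_signal)) {
    sig[, , k] <- truth + generate_noise_roi(model, roi_side,
                                             derive_seed(seed, "signal", k))
  }
  noi <- array(0, dim = c(roi_side, roi_side, n_noise))
  for (k in seq_len(n_noise)) {
    noi[, , k] <- generate_noise_roi(model, roi_side, derive_seed(seed, "noise", k))
  }
  structure(list(category = category, model = model, signal = sig, noise = noi,
                 truth = unclass(truth), pixel_pitch = pixel_pitch, seed = seed),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset %s: %d signal-present + %d signal-absent %dx%d ROIs, seed %d>\n",
              format(x$category), dim(x$signal)[3L], dim(x$noise)[3L],
              dim(x$signal)[1L], dim(x$signal)[2L], x$seed))
  invisible(x)
}

n_signal_rois <- function(dataset) dim(dataset$signal)[3L]
n_noise_rois <- function(dataset) dim(dataset$noise)[3L]
roi_side_of <- function(dataset) dim(dataset$signal)[1L]
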