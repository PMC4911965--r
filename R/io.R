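# Serialisation: ROI stacks (raw float32 or multi-page TIFF, each with a JSON
# sidecar), CHO templates as JSON, channel banks, and the study results CSV.

#' Write / read an ROI dataset
#'
#' Writes the signal-present ROIs, signal-absent ROIs and the noise-free
#' truth profile as one stack, plus a JSON sidecar (`<stem>.json`) carrying
#' the category, noise model, counts, geometry and seed. Two stack formats:
#'
#' * `"raw"` (default): little-endian 32-bit floats in page order
#'   signal, noise, truth (`<stem>.raw`). Values round-trip at float32
#'   precision.
#' * `"tiff"`: multi-page TIFF (`<stem>.tif`). TIFF pages are stored
#'   rescaled to \[0, 1\]; the affine rescale (slope/intercept) that maps
#'   stored values back to HU is recorded in the sidecar.
#'
#' @param dataset A `roi_dataset`.
#' @param stem Path without extension; the writer adds `.raw`/`.tif` and
#'   `.json`.
#' @param format `"raw"` or `"tiff"`.
#'
#' @return `write_roi_dataset()` returns `stem` invisibly;
#'   `read_roi_dataset()` returns the reconstituted `roi_dataset`.
#' @export
write_roi_dataset <- function(dataset, stem, format = c("raw", "tiff")) {
  stopifnot(inherits(dataset, "roi_dataset"))
  format <- match.arg(format)
  side <- roi_side_of(dataset)
  pages <- c(lapply(seq_len(n_signal_rois(dataset)), function(k) dataset$signal[, , k]),
             lapply(seq_len(n_noise_rois(dataset)), function(k) dataset$noise[, , k]),
             list(dataset$truth))
  sidecar <- list(format = format, roi_side = side,
                  pixel_pitch = dataset$pixel_pitch,
                  n_signal = n_signal_rois(dataset),
                  n_noise = n_noise_rois(dataset),
                  page_order = "signal, noise, truth",
                  seed = dataset$seed,
                  category = unclass(dataset$category),
                  noise_model = unclass(dataset$model))
  if (format == "raw") {
    sidecar$dtype <- "float32"
    sidecar$endianness <- "little"
    con <- file(paste0(stem, ".raw"), "wb")
    on.exit(close(con))
    for (p in pages) writeBin(as.vector(p), con, size = 4L, endian = "little")
  } else {
    lo <- min(vapply(pages, min, 0)); hi <- max(vapply(pages, max, 0))
    slope <- if (hi > lo) hi - lo else 1
    sidecar$rescale_slope <- slope
    sidecar$rescale_intercept <- lo
    scaled <- lapply(pages, function(p) (p - lo) / slope)
    tiff::writeTIFF(scaled, paste0(stem, ".tif"), bits.per.sample = 32L,
                    reduce = FALSE)
  }
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_roi_dataset
#' @export
read_roi_dataset <- function(stem) {
  sc <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  side <- sc$roi_side
  n_pages <- sc$n_signal + sc$n_noise + 1L
  if (sc$format == "raw") {
    con <- file(paste0(stem, ".raw"), "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = side * side * n_pages, size = 4L,
                    endian = "little")
    pages <- array(vals, dim = c(side, side, n_pages))
  } else {
    raw_pages <- tiff::readTIFF(paste0(stem, ".tif"), all = TRUE)
    pages <- array(0, dim = c(side, side, n_pages))
    for (k in seq_len(n_pages)) {
      pages[, , k] <- raw_pages[[k]] * sc$rescale_slope + sc$rescale_intercept
    }
  }
  i_sig <- seq_len(sc$n_signal)
  i_noi <- sc$n_signal + seq_len(sc$n_noise)
  structure(list(category = do.call(category, sc$category),
                 model = do.call(noise_model, sc$noise_model),
                 signal = pages[, , i_sig, drop = FALSE],
                 noise = pages[, , i_noi, drop = FALSE],
                 truth = pages[, , n_pages],
                 pixel_pitch = sc$pixel_pitch, seed = sc$seed),
            class = "roi_dataset")
}

#' Write / read a CHO template as JSON
#'
#' Serialises the template vector, class means, channel-space covariance
#' matrices and training counts as nested JSON arrays, together with the
#' channel-bank parameter block for provenance.
#'
#' @param template A `cho_template`.
#' @param path Output `.json` path.
#' @param bank Optional `channel_bank` whose parameters are recorded.
#'
#' @return `write_cho_template()` returns `path` invisibly;
#'   `read_cho_template()` returns the `cho_template`.
#' @export
write_cho_template <- function(template, path, bank = NULL) {
  stopifnot(inherits(template, "cho_template"))
  payload <- list(w = template$w,
                  mean_signal_c = template$mean_signal_c,
                  mean_noise_c = template$mean_noise_c,
                  cov_signal_c = template$cov_signal_c,
                  cov_noise_c = template$cov_noise_c,
                  n_train_signal = template$n_train_signal,
                  n_train_noise = template$n_train_noise,
                  ridge = template$ridge)
  if (!is.null(bank)) {
    payload$bank <- list(params = unclass(bank$params), roi_side = bank$roi_side,
                         pixel_pitch = bank$pixel_pitch)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cho_template
#' @export
read_cho_template <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.vector(p$w),
                 mean_signal_c = as.vector(p$mean_signal_c),
                 mean_noise_c = as.vector(p$mean_noise_c),
                 cov_signal_c = as.matrix(p$cov_signal_c),
                 cov_noise_c = as.matrix(p$cov_noise_c),
                 n_train_signal = p$n_train_signal,
                 n_train_noise = p$n_train_noise,
                 ridge = p$ridge),
            class = "cho_template")
}

#' Write / read a channel bank
#'
#' The spatial templates go to `<stem>.raw` (little-endian 64-bit floats,
#' one page per channel, exact) and the defining parameters to
#' `<stem>.json`; the reader checks that rebuilding the bank from the
#' parameters reproduces the stored matrix.
#'
#' @param bank A `channel_bank`.
#' @param stem Path without extension.
#'
#' @return `write_channel_bank()` returns `stem` invisibly;
#'   `read_channel_bank()` the `channel_bank`.
#' @export
write_channel_bank <- function(bank, stem) {
  stopifnot(inherits(bank, "channel_bank"))
  con <- file(paste0(stem, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(bank$U), con, size = 8L, endian = "little")
  jsonlite::write_json(list(params = unclass(bank$params),
                            roi_side = bank$roi_side,
                            pixel_pitch = bank$pixel_pitch,
                            dtype = "float64", endianness = "little"),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_channel_bank
#' @export
read_channel_bank <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- meta$roi_side^2 * meta$params$n_channels
  con <- file(paste0(stem, ".raw"), "rb")
  on.exit(close(con))
  u <- readBin(con, numeric(), n = n, size = 8L, endian = "little")
  structure(list(U = matrix(u, meta$roi_side^2, meta$params$n_channels),
                 params = do.call(channel_params, meta$params),
                 roi_side = meta$roi_side, pixel_pitch = meta$pixel_pitch),
            class = "channel_bank")
}

#' Write / read the study results table
#'
#' CSV serialisation of a [run_study()] table; doubles are written with
#' shortest round-trip precision so write -> read is lossless.
#'
#' @param results A `study_results` tibble.
#' @param path CSV path.
#'
#' @return `write_study_results()` returns `path` invisibly;
#'   `read_study_results()` the tibble (class restored).
#' @export
write_study_results <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}

#' @rdname write_study_results
#' @export
read_study_results <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           recon_strength = readr::col_integer(),
                           n_trials = readr::col_integer(),
                           seed = readr::col_integer(),
                           status = readr::col_character()))
  class(out) <- c("study_results", class(out))
  out
}
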