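# Factorial study orchestration: category grid -> synthetic datasets -> CHO
# training -> 4-AFC -> bootstrap, one tidy row per category. Also ROI
# extraction from user-supplied slice stacks.

#' Configuration for a factorial detectability study
#'
#' Collects the acquisition grid (dose levels, reconstruction strengths,
#' contrasts, diameters), the ROI geometry, channel parameters, the noise
#' surrogate, the per-category counts and the master seed. Defaults
#' reproduce the standard 32-category design: doses {1.0, 3.5, 8.0, 15.0}
#' mGy, reconstruction strengths {1, 3}, contrasts {10, 20} HU, diameters
#' {6, 8} mm, 100 signal-present and 1000 signal-absent 41x41 ROIs at
#' 0.59 mm/pixel, and 150 bootstrap replicates.
#'
#' The synthetic noise magnitude at each dose comes from
#' [dose_to_sigma()] anchored at (`reference_dose_mGy`,
#' `reference_sigma_hu`), multiplied by a per-strength factor from
#' `recon_sigma_scale` — a surrogate for the noise reduction of iterative
#' reconstruction (strength 1 leaves noise unchanged; stronger levels shrink
#' it).
#'
#' @param dose_levels_mGy,recon_strengths,contrasts_hu,diameters_mm The
#'   factorial grid; all non-empty.
#' @param roi_side,pixel_pitch ROI geometry.
#' @param params A [channel_params()].
#' @param noise_kind `"white"` or `"nps_shaped"` (see [noise_model()]).
#' @param reference_sigma_hu,reference_dose_mGy Anchor of the quantum-noise
#'   scaling.
#' @param nps_exponent Spectral exponent for `"nps_shaped"` noise.
#' @param recon_sigma_scale Named or positional numeric vector of length 5:
#'   noise-SD multiplier for reconstruction strengths 1..5.
#' @param n_signal,n_noise,n_boot Per-category counts.
#' @param m_alternatives Alternatives per forced-choice trial.
#' @param master_seed Master seed for the whole study.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(dose_levels_mGy = c(1.0, 3.5, 8.0, 15.0),
                         recon_strengths = c(1L, 3L),
                         contrasts_hu = c(10, 20),
                         diameters_mm = c(6, 8),
                         roi_side = 41L, pixel_pitch = 0.59,
                         params = channel_params(),
                         noise_kind = c("white", "nps_shaped"),
                         reference_sigma_hu = 10, reference_dose_mGy = 15,
                         nps_exponent = 1,
                         recon_sigma_scale = c(1.00, 0.90, 0.80, 0.70, 0.60),
                         n_signal = 100L, n_noise = 1000L, n_boot = 150L,
                         m_alternatives = 4L, master_seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  for (nm in c("dose_levels_mGy", "recon_strengths", "contrasts_hu", "diameters_mm")) {
    v <- get(nm)
    if (length(v) < 1L) abort(sprintf("`%s` must be non-empty", nm))
  }
  if (any(dose_levels_mGy <= 0)) abort("dose levels must be positive")
  if (any(!recon_strengths %in% 1:5)) abort("reconstruction strengths must be in 1..5")
  if (length(recon_sigma_scale) != 5L || any(recon_sigma_scale <= 0)) {
    abort("`recon_sigma_scale` must give one positive multiplier per strength 1..5")
  }
  structure(list(dose_levels_mGy = as.double(dose_levels_mGy),
                 recon_strengths = as.integer(recon_strengths),
                 contrasts_hu = as.double(contrasts_hu),
                 diameters_mm = as.double(diameters_mm),
                 roi_side = assert_count(roi_side, "roi_side", 3L),
                 pixel_pitch = assert_positive(pixel_pitch, "pixel_pitch"),
                 params = params, noise_kind = noise_kind,
                 reference_sigma_hu = assert_positive(reference_sigma_hu, "reference_sigma_hu"),
                 reference_dose_mGy = assert_positive(reference_dose_mGy, "reference_dose_mGy"),
                 nps_exponent = as.double(nps_exponent),
                 recon_sigma_scale = as.double(recon_sigma_scale),
                 n_signal = assert_count(n_signal, "n_signal", 1L),
                 n_noise = assert_count(n_noise, "n_noise", 4L),
                 n_boot = assert_count(n_boot, "n_boot", 2L),
                 m_alternatives = assert_count(m_alternatives, "m_alternatives", 2L),
                 master_seed = assert_count(master_seed, "master_seed", 0L)),
            class = "study_config")
}

#' Enumerate the category grid of a study
#'
#' Cartesian product of the configured factor levels in deterministic order:
#' dose varies slowest (outermost), then reconstruction strength, then
#' contrast, with diameter innermost.
#'
#' @param config A [study_config()].
#'
#' @return A tibble with columns `dose_mGy`, `recon_strength`, `contrast_hu`,
#'   `diameter_mm`, one row per category.
#' @export
#' @examples
#' nrow(enumerate_categories(study_config()))  # 32
enumerate_categories <- function(config) {
  stopifnot(inherits(config, "study_config"))
  tidyr::expand_grid(dose_mGy = config$dose_levels_mGy,
                     recon_strength = config$recon_strengths,
                     contrast_hu = config$contrasts_hu,
                     diameter_mm = config$diameters_mm)
}

#' Run the full factorial detectability study
#'
#' For every category: derive the noise SD from dose and reconstruction
#' strength, generate the synthetic dataset, train the CHO by resubstitution,
#' and bootstrap the 4-AFC percent correct. The channel bank is built once.
#' Per-category seeds derive from the master seed and the category index, so
#' a rerun with the same config is bit-identical. A category that errors is
#' reported as a flagged row (`status` column) and the remaining categories
#' proceed.
#'
#' @param config A [study_config()].
#' @param progress Print a line per category?
#'
#' @return A tibble of class `study_results`: the category columns plus
#'   `sigma_hu`, `dprime`, `pc_mean`, `pc_sd`, `ci95_low`, `ci95_high`,
#'   `n_trials`, `seed`, `status`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  grid <- enumerate_categories(config)
  bank <- build_channel_bank(config$roi_side, config$pixel_pitch, config$params)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cat_seed <- derive_seed(config$master_seed, "category", i)
    res <- tibble(g, sigma_hu = NA_real_, dprime = NA_real_, pc_mean = NA_real_,
                  pc_sd = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
                  n_trials = NA_integer_, seed = cat_seed, status = "ok")
    tryCatch({
      sigma <- dose_to_sigma(g$dose_mGy, config$reference_sigma_hu,
                             config$reference_dose_mGy) *
        config$recon_sigma_scale[g$recon_strength]
      model <- noise_model(config$noise_kind, sigma_hu = sigma,
                           nps_exponent = config$nps_exponent)
      cat_i <- category(g$dose_mGy, g$recon_strength, g$contrast_hu, g$diameter_mm)
      ds <- generate_category_dataset(cat_i, model, config$n_signal,
                                      config$n_noise, seed = cat_seed,
                                      roi_side = config$roi_side,
                                      pixel_pitch = config$pixel_pitch)
      tmpl <- train_cho(ds$signal, ds$noise, bank)
      boot <- bootstrap_pc(tmpl, bank, ds, n_boot = config$n_boot,
                           seed = derive_seed(cat_seed, "boot"),
                           m_alternatives = config$m_alternatives)
      res$sigma_hu <- sigma
      res$dprime <- detectability_index(tmpl)
      res$pc_mean <- boot$pc_mean
      res$pc_sd <- boot$pc_sd
      res$ci95_low <- boot$ci95_low
      res$ci95_high <- boot$ci95_high
      res$n_trials <- config$n_signal
      res
    }, error = function(e) {
      warn(sprintf("category %d (%g mGy, strength %d, %g HU, %g mm) failed: %s",
                   i, g$dose_mGy, g$recon_strength, g$contrast_hu, g$diameter_mm,
                   conditionMessage(e)))
      res$status <- paste0("error: ", conditionMessage(e))
      res
    })
  })
  if (progress) {
    purrr::walk(rows, function(r) {
      cat(sprintf("%5.1f mGy  strength %d  %2g HU  %g mm  PC %.1f%%\n",
                  r$dose_mGy, r$recon_strength, r$contrast_hu, r$diameter_mm,
                  r$pc_mean))
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("study_results", class(out))
  attr(out, "config") <- config
  out
}

#' Extract ROIs from a slice stack
#'
#' Cuts square ROIs of side `roi_side` centred on given pixel coordinates
#' out of an image series (3-D array `[row, col, slice]`, or a list of
#' matrices). Coordinates are 0-based with `x` = column and `y` = row; the
#' ROI spans the closed square of side `roi_side` centred on the given pixel
#' and must lie fully inside its slice. Raw values are converted to HU with
#' `value * rescale_slope + rescale_intercept` when a rescale is supplied;
#' otherwise values pass through with a warning.
#'
#' @param slices 3-D numeric array or list of equal-sized matrices.
#' @param centers Data frame with 0-based columns `x`, `y`, `slice` and an
#'   optional `role` column (`"signal"`/`"noise"`, default all signal).
#' @param roi_side ROI side length (odd).
#' @param pixel_pitch Pixel size in mm recorded in the output.
#' @param rescale_slope,rescale_intercept Linear HU rescale; `NULL` means
#'   the source carries no rescale and raw values are kept.
#' @param category Optional [category()] recorded in the output.
#' @param truth Optional noise-free signal profile to record.
#' @param seed Seed value recorded in the output metadata (extraction itself
#'   is deterministic).
#'
#' @return A `roi_dataset`. Datasets with no noise ROIs get a 0-extent
#'   noise array.
#' @export
extract_rois <- function(slices, centers, roi_side = 41L, pixel_pitch = 0.59,
                         rescale_slope = NULL, rescale_intercept = NULL,
                         category = NULL, truth = NULL, seed = 0L) {
  roi_side <- assert_count(roi_side, "roi_side", min = 3L)
  if (roi_side %% 2L == 0L) abort("`roi_side` must be odd")
  if (is.list(slices)) {
    slices <- array(unlist(slices, use.names = FALSE),
                    dim = c(nrow(slices[[1L]]), ncol(slices[[1L]]), length(slices)))
  }
  stopifnot(is.array(slices), length(dim(slices)) == 3L)
  centers <- as_tibble(centers)
  if (!all(c("x", "y", "slice") %in% names(centers))) {
    abort("`centers` needs 0-based columns `x`, `y`, `slice`")
  }
  if (!"role" %in% names(centers)) centers$role <- "signal"
  h <- (roi_side - 1L) %/% 2L
  nr <- dim(slices)[1L]; ncl <- dim(slices)[2L]; nsl <- dim(slices)[3L]
  # 1-based index windows from 0-based centres
  row0 <- centers$y + 1L - h; row1 <- centers$y + 1L + h
  col0 <- centers$x + 1L - h; col1 <- centers$x + 1L + h
  sl <- centers$slice + 1L
  bad <- which(row0 < 1L | row1 > nr | col0 < 1L | col1 > ncl | sl < 1L | sl > nsl)
  if (length(bad)) {
    abort(paste0("ROI crosses the image boundary at centre(s): ",
                 paste(sprintf("(x=%d, y=%d, slice=%d)", centers$x[bad],
                               centers$y[bad], centers$slice[bad]),
                       collapse = ", ")))
  }
  if (is.null(rescale_slope) || is.null(rescale_intercept)) {
    warn("no rescale slope/intercept supplied; keeping raw pixel values")
    rescale_slope <- 1; rescale_intercept <- 0
  }
  cut_one <- function(k) {
    slices[row0[k]:row1[k], col0[k]:col1[k], sl[k]] * rescale_slope + rescale_intercept
  }
  take <- function(rows) {
    if (!length(rows)) return(array(0, dim = c(roi_side, roi_side, 0L)))
    array(vapply(rows, cut_one, matrix(0, roi_side, roi_side)),
          dim = c(roi_side, roi_side, length(rows)))
  }
  structure(list(category = category %||% category_unknown(),
                 model = noise_model("white", sigma_hu = 0),
                 signal = take(which(centers$role == "signal")),
                 noise = take(which(centers$role == "noise")),
                 truth = truth %||% matrix(0, roi_side, roi_side),
                 pixel_pitch = pixel_pitch, seed = as.integer(seed)),
            class = "roi_dataset")
}

# Placeholder category for user-supplied data with no acquisition metadata.
category_unknown <- function() category(1, 1L, 0, 1)

#' @rdname run_study
#' @param x A `study_results` tibble.
#' @param ... Unused.
#' @method glance study_results
#' @export
glance.study_results <- function(x, ...) {
  tibble(n_categories = nrow(x), n_ok = sum(x$status == "ok"),
         pc_min = min(x$pc_mean, na.rm = TRUE),
         pc_max = max(x$pc_mean, na.rm = TRUE))
}
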