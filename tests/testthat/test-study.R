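# Factorial orchestration, category enumeration and ROI extraction.

test_that("the default design enumerates 32 categories in documented order", {
  grid <- enumerate_categories(study_config())
  expect_equal(nrow(grid), 32L)
  expect_equal(names(grid), c("dose_mGy", "recon_strength", "contrast_hu", "diameter_mm"))
  # dose outermost, diameter innermost
  expect_equal(grid$dose_mGy, rep(c(1.0, 3.5, 8.0, 15.0), each = 8))
  expect_equal(grid$diameter_mm, rep(c(6, 8), times = 16))

  one <- study_config(dose_levels_mGy = 3.5, recon_strengths = 1L,
                      contrasts_hu = 10, diameters_mm = 6)
  expect_equal(nrow(enumerate_categories(one)), 1L)

  cfg6 <- study_config(dose_levels_mGy = c(1, 2, 3), recon_strengths = c(1L, 3L),
                       contrasts_hu = 10, diameters_mm = 6)
  grid6 <- enumerate_categories(cfg6)
  # brute-force product enumeration oracle
  ref <- expand.grid(diameter_mm = 6, contrast_hu = 10,
                     recon_strength = c(1L, 3L), dose_mGy = c(1, 2, 3))
  ref <- ref[order(ref$dose_mGy, ref$recon_strength), c(4, 3, 2, 1)]
  expect_equal(as.data.frame(grid6), ref, ignore_attr = TRUE)

  expect_error(study_config(dose_levels_mGy = numeric(0)), "non-empty")
})

small_cfg <- function(...) {
  study_config(dose_levels_mGy = c(2, 10), recon_strengths = 1L,
               contrasts_hu = 10, diameters_mm = 4,
               roi_side = 21L, params = tiny_params,
               n_signal = 25L, n_noise = 100L, n_boot = 10L,
               reference_sigma_hu = 8, master_seed = 7L, ...)
}

test_that("run_study yields one tidy row per category and is reproducible", {
  res <- run_study(small_cfg())
  expect_s3_class(res, "study_results")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$pc_mean >= 0 & res$pc_mean <= 100))
  expect_true(all(res$ci95_low <= res$pc_mean & res$pc_mean <= res$ci95_high))
  # noisier low-dose category has larger sigma and lower d'
  expect_gt(res$sigma_hu[1], res$sigma_hu[2])
  expect_lt(res$dprime[1], res$dprime[2])

  res2 <- run_study(small_cfg())
  expect_equal(as.data.frame(res), as.data.frame(res2))
  expect_equal(glance(res)$n_ok, 2L)
})

test_that("a zero-contrast study sits at chance", {
  cfg <- study_config(dose_levels_mGy = 10, recon_strengths = 1L,
                      contrasts_hu = 0, diameters_mm = 4,
                      roi_side = 21L, params = tiny_params,
                      n_signal = 100L, n_noise = 400L,
                      n_boot = 30L, reference_sigma_hu = 8, master_seed = 3L)
  res <- run_study(cfg)
  se_chance <- 100 * sqrt(0.25 * 0.75 / 100)
  expect_lt(abs(res$pc_mean - 25), 3 * max(se_chance, res$pc_sd))
})

test_that("PC is non-decreasing along the dose ladder at fixed seeds", {
  cfg <- study_config(recon_strengths = 1L, contrasts_hu = 10, diameters_mm = 6,
                      roi_side = 21L, params = tiny_params,
                      n_signal = 50L, n_noise = 200L,
                      n_boot = 30L, reference_sigma_hu = 8, master_seed = 19L)
  res <- run_study(cfg)
  expect_equal(res$dose_mGy, c(1.0, 3.5, 8.0, 15.0))
  jump <- diff(res$pc_mean)
  expect_true(all(jump >= -2 * res$pc_sd[-1]))
})

test_that("extract_rois cuts the advertised closed square and round-trips", {
  # 0-based centre (256, 256) on a 512-wide slice spans 0-based rows/cols
  # 236..276, i.e. 1-based 237..277
  slice <- matrix(rnorm(512 * 512), 512, 512)
  ds <- suppressWarnings(
    extract_rois(array(slice, c(512, 512, 1)),
                 data.frame(x = 256, y = 256, slice = 0), roi_side = 41L))
  expect_identical(ds$signal[, , 1], slice[237:277, 237:277])

  # round trip: a generated ROI embedded in a larger slice comes back bit-for-bit
  prof <- make_signal_profile(6, 10, roi_side = 41L)
  noisy <- matrix(as.numeric(prof), 41L, 41L) +
    generate_noise_roi(noise_model("white", 5), 41L, 3L)
  big <- matrix(0, 128, 128)
  big[40:80, 50:90] <- noisy
  ds2 <- extract_rois(array(big, c(128, 128, 1)),
                      data.frame(x = 69, y = 59, slice = 0), roi_side = 41L,
                      rescale_slope = 1, rescale_intercept = 0)
  expect_identical(ds2$signal[, , 1], noisy)

  # rescale slope/intercept converts raw values to HU
  ds3 <- extract_rois(array(big / 2 + 10, c(128, 128, 1)),
                      data.frame(x = 69, y = 59, slice = 0), roi_side = 41L,
                      rescale_slope = 2, rescale_intercept = -20)
  expect_equal(ds3$signal[, , 1], noisy, tolerance = 1e-12)

  expect_error(extract_rois(array(big, c(128, 128, 1)),
                            data.frame(x = 10, y = 10, slice = 0), roi_side = 41L),
               "boundary.*x=10")
  expect_warning(extract_rois(array(big, c(128, 128, 1)),
                              data.frame(x = 69, y = 59, slice = 0), 41L),
                 "rescale")
})

test_that("study results round-trip through CSV losslessly", {
  res <- run_study(small_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_results(res, path)
  back <- read_study_results(path)
  attr(res, "config") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(res))
})
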