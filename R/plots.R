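# ggplot2 displays for study results, bootstrap distributions, channel
# profiles and single ROIs.

#' Plot percent correct against dose
#'
#' One panel per (contrast, diameter) cell, PC versus CTDI_vol with
#' 95% confidence ribbons, coloured by reconstruction strength — the
#' standard dose-response display for a factorial detectability study.
#'
#' @param object A `study_results` tibble from [run_study()].
#' @param ... Unused.
#'
#' @return A ggplot.
#' @method autoplot study_results
#' @export
autoplot.study_results <- function(object, ...) {
  df <- dplyr::filter(object, .data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_mGy, y = .data$pc_mean,
                                   colour = factor(.data$recon_strength),
                                   fill = factor(.data$recon_strength))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_low, ymax = .data$ci95_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(contrast_hu ~ diameter_mm,
                        labeller = ggplot2::labeller(
                          contrast_hu = function(v) paste0(v, " HU"),
                          diameter_mm = function(v) paste0(v, " mm"))) +
    ggplot2::labs(x = expression(CTDI[vol] ~ "(mGy)"), y = "Percent correct (%)",
                  colour = "Recon strength", fill = "Recon strength") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_bw()
}

#' Plot the bootstrap PC distribution
#'
#' @param object A `pc_bootstrap` from [bootstrap_pc()].
#' @param ... Unused.
#'
#' @return A ggplot.
#' @method autoplot pc_bootstrap
#' @export
autoplot.pc_bootstrap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$pc_mean, linetype = 2) +
    ggplot2::labs(x = "Percent correct (%)", y = "Bootstrap replicates") +
    ggplot2::theme_bw()
}

#' Plot channel radial frequency profiles
#'
#' @param object A `channel_bank`.
#' @param ... Unused.
#'
#' @return A ggplot of each channel's response against radial frequency.
#' @method autoplot channel_bank
#' @export
autoplot.channel_bank <- function(object, ...) {
  rho <- seq(0, 0.5, length.out = 512)
  df <- purrr::map_dfr(seq_len(object$params$n_channels), function(j) {
    tibble(rho = rho, response = ddog_profile(rho, j, object$params),
           channel = factor(j))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$response,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Radial frequency (cycles/pixel)", y = "Response",
                  colour = "Channel") +
    ggplot2::theme_bw()
}

#' Display a single ROI
#'
#' @param roi An ROI matrix.
#' @param title Optional plot title.
#'
#' @return A ggplot raster image in greyscale HU.
#' @export
plot_roi <- function(roi, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(roi)), col = seq_len(ncol(roi)))
  df$hu <- as.vector(t(roi))[(df$row - 1L) * ncol(roi) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
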