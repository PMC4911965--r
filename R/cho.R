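# Channelised Hotelling observer: template training in channel space and the
# scalar decision variable.

#' Train a channelised Hotelling observer template
#'
#' Projects the training ROIs onto the channel bank, estimates class means
#' and unbiased sample covariances in channel space, and solves
#' `[0.5 (K_cs + K_cn) + ridge I] w = (mean_signal_c - mean_noise_c)`
#' by a linear solve (no explicit inverse). With the default `ridge = 0`, a
#' numerically singular system triggers an automatic ridge of
#' `1e-8 * trace / n_channels` with a warning.
#'
#' @param signal_rois Signal-present training ROIs: 3-D array
#'   (side x side x n) or list of matrices.
#' @param noise_rois Signal-absent training ROIs, same formats.
#' @param bank A [build_channel_bank()] result.
#' @param ridge Non-negative Tikhonov term added to the average covariance.
#'
#' @return A list of class `cho_template` with elements `w` (length
#'   n_channels), `mean_signal_c`, `mean_noise_c`, `cov_signal_c`,
#'   `cov_noise_c`, `n_train_signal`, `n_train_noise`, `ridge`.
#' @export
#' @examples
#' bank <- build_channel_bank(15)
#' cat5 <- category(15, 1, contrast_hu = 20, diameter_mm = 4)
#' ds <- generate_category_dataset(cat5, noise_model("white", 5),
#'                                 n_signal = 20, n_noise = 40, seed = 7,
#'                                 roi_side = 15)
#' tmpl <- train_cho(ds$signal, ds$noise, bank)
train_cho <- function(signal_rois, noise_rois, bank, ridge = 0) {
  stopifnot(inherits(bank, "channel_bank"))
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0) {
    abort("`ridge` must be a single number >= 0")
  }
  gs <- channelize_stack(signal_rois, bank)
  gn <- channelize_stack(noise_rois, bank)
  if (ncol(gs) < 2L || ncol(gn) < 2L) {
    abort("training needs at least 2 ROIs in each class for a sample covariance")
  }
  if (!all(is.finite(gs)) || !all(is.finite(gn))) {
    abort("non-finite channel outputs in the training data")
  }
  mean_s <- rowMeans(gs)
  mean_n <- rowMeans(gn)
  k_s <- cov(t(gs))
  k_n <- cov(t(gn))
  nc <- bank$params$n_channels
  s_bar <- 0.5 * (k_s + k_n) + diag(ridge, nc)
  dmean <- mean_s - mean_n
  w <- tryCatch(solve(s_bar, dmean), error = function(e) {
    auto <- 1e-8 * sum(diag(s_bar)) / nc
    warn(sprintf("average channel covariance numerically singular; retrying with ridge %.3g", auto))
    solve(s_bar + diag(auto, nc), dmean)
  })
  structure(list(w = as.vector(w), mean_signal_c = mean_s, mean_noise_c = mean_n,
                 cov_signal_c = k_s, cov_noise_c = k_n,
                 n_train_signal = ncol(gs), n_train_noise = ncol(gn),
                 ridge = as.double(ridge)),
            class = "cho_template")
}

#' @export
print.cho_template <- function(x, ...) {
  cat(sprintf("<cho_template: %d channels, trained on %d signal / %d noise ROIs>\n",
              length(x$w), x$n_train_signal, x$n_train_noise))
  invisible(x)
}

#' CHO decision variable
#'
#' The scalar test statistic `lambda = t(w) %*% (t(U) %*% g)`: the trained
#' template applied to the channel outputs of an ROI. Because channels have
#' zero mean, adding a constant to every pixel leaves lambda unchanged.
#'
#' @param roi An ROI matrix matching the bank geometry.
#' @param template A [train_cho()] result.
#' @param bank The [build_channel_bank()] the template was trained with.
#'
#' @return A single numeric lambda.
#' @export
decision_variable <- function(roi, template, bank) {
  stopifnot(inherits(template, "cho_template"))
  sum(template$w * apply_channels(roi, bank))
}

# Decision variables for a whole stack: numeric vector of length n.
decision_variables_stack <- function(rois, template, bank) {
  drop(crossprod(channelize_stack(rois, bank), template$w))
}

#' Channel-space detectability index
#'
#' The prewhitened signal-to-noise ratio of the trained observer:
#' `d' = sqrt(t(dm) %*% solve(0.5 (K_cs + K_cn)) %*% dm)` with `dm` the
#' channel-space class-mean difference. For Gaussian channel outputs with
#' equal class covariances, d' links the 4-AFC percent correct to the
#' closed form in [pc_closed_form()].
#'
#' @param template A [train_cho()] result.
#'
#' @return A single non-negative number.
#' @export
detectability_index <- function(template) {
  stopifnot(inherits(template, "cho_template"))
  s_bar <- 0.5 * (template$cov_signal_c + template$cov_noise_c)
  dm <- template$mean_signal_c - template$mean_noise_c
  q <- tryCatch(drop(crossprod(dm, solve(s_bar, dm))), error = function(e) {
    abort("average channel covariance is singular; retrain with a positive `ridge`")
  })
  sqrt(max(q, 0))
}

#' @rdname train_cho
#' @param x A `cho_template`.
#' @param ... Unused.
#' @method tidy cho_template
#' @export
tidy.cho_template <- function(x, ...) {
  tibble(channel = seq_along(x$w), weight = x$w,
         mean_signal_c = x$mean_signal_c, mean_noise_c = x$mean_noise_c)
}

#' @rdname train_cho
#' @method glance cho_template
#' @export
glance.cho_template <- function(x, ...) {
  tibble(n_channels = length(x$w), n_train_signal = x$n_train_signal,
         n_train_noise = x$n_train_noise, ridge = x$ridge,
         dprime = detectability_index(x))
}
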