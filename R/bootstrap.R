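# Bootstrap uncertainty on the percent correct, and the matching summary for
# human-reader PC tables.

#' Bootstrap the 4-AFC percent correct
#'
#' Each replicate resamples the signal-present collection with replacement to
#' its original size, runs a full forced-choice pass against the fixed noise
#' pool, and records the PC. The summary is the mean and standard deviation
#' of the replicate PCs and a normal-approximation 95% confidence interval
#' `mean +/- 1.96 SD`, clipped to [0, 100]. The template is trained once and
#' held fixed across replicates unless `refit_per_replicate = TRUE`, in which
#' case it is retrained on each resampled signal set.
#'
#' @param template A [train_cho()] result.
#' @param bank The matching [build_channel_bank()].
#' @param dataset A `roi_dataset`.
#' @param n_boot Number of bootstrap replicates (default 150, >= 2).
#' @param seed Integer seed.
#' @param m_alternatives Alternatives per trial (default 4).
#' @param refit_per_replicate Retrain the template inside every replicate?
#'
#' @return A list of class `pc_bootstrap` with `n_boot`, `pc_values`,
#'   `pc_mean`, `pc_sd`, `ci95_low`, `ci95_high`, `seed`.
#' @export
bootstrap_pc <- function(template, bank, dataset, n_boot = 150L, seed = 1L,
                         m_alternatives = 4L, refit_per_replicate = FALSE) {
  stopifnot(inherits(dataset, "roi_dataset"))
  n_boot <- assert_count(n_boot, "n_boot", min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  ns <- n_signal_rois(dataset)
  lam_n <- decision_variables_stack(dataset$noise, template, bank)
  lam_s <- decision_variables_stack(dataset$signal, template, bank)
  pc_values <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rep_seed <- derive_seed(seed, "boot", b)
    set.seed(rep_seed)
    idx <- sample.int(ns, ns, replace = TRUE)
    if (refit_per_replicate) {
      tmpl_b <- train_cho(dataset$signal[, , idx, drop = FALSE], dataset$noise,
                          bank, ridge = template$ridge)
      ls_b <- decision_variables_stack(dataset$signal[, , idx, drop = FALSE], tmpl_b, bank)
      ln_b <- decision_variables_stack(dataset$noise, tmpl_b, bank)
    } else {
      ls_b <- lam_s[idx]
      ln_b <- lam_n
    }
    out <- run_afc_scores(ls_b, ln_b, m_alternatives = m_alternatives,
                          seed = derive_seed(rep_seed, "afc"), signal_ids = idx)
    pc_values[b] <- out$pc
  }
  pc_mean <- mean(pc_values)
  pc_sd <- sd(pc_values)
  structure(list(n_boot = n_boot, pc_values = pc_values, pc_mean = pc_mean,
                 pc_sd = pc_sd,
                 ci95_low = max(0, pc_mean - 1.96 * pc_sd),
                 ci95_high = min(100, pc_mean + 1.96 * pc_sd),
                 seed = seed),
            class = "pc_bootstrap")
}

#' @export
print.pc_bootstrap <- function(x, ...) {
  cat(sprintf("<pc_bootstrap: %d replicates, PC = %.1f%% +/- %.1f (95%% CI %.1f-%.1f)>\n",
              x$n_boot, x$pc_mean, x$pc_sd, x$ci95_low, x$ci95_high))
  invisible(x)
}

#' @rdname bootstrap_pc
#' @param x A `pc_bootstrap`.
#' @param ... Unused.
#' @method tidy pc_bootstrap
#' @export
tidy.pc_bootstrap <- function(x, ...) {
  tibble(replicate = seq_len(x$n_boot), pc = x$pc_values)
}

#' @rdname bootstrap_pc
#' @method glance pc_bootstrap
#' @export
glance.pc_bootstrap <- function(x, ...) {
  tibble(n_boot = x$n_boot, pc_mean = x$pc_mean, pc_sd = x$pc_sd,
         ci95_low = x$ci95_low, ci95_high = x$ci95_high, seed = x$seed)
}

#' Summarise human-reader PCs per category
#'
#' Takes a long table with one PC per observer and category, and returns the
#' per-category mean PC with a standard-error-based 95% confidence interval
#' (`mean +/- 1.96 * SD / sqrt(n_observers)`), the convention used when a
#' handful of readers each contribute one PC per condition.
#'
#' @param per_observer_pcs Data frame with an observer column, a `pc` column
#'   (percent), and any number of category-identifying columns.
#' @param observer_col Name of the observer column (default `"observer"`).
#' @param pc_col Name of the PC column (default `"pc"`).
#'
#' @return A tibble with one row per category: grouping columns,
#'   `n_observers`, `pc_mean`, `pc_se`, `ci95_low`, `ci95_high`.
#' @export
#' @examples
#' df <- tidyr::expand_grid(observer = c("A", "B", "C"), dose_mGy = c(1, 3.5))
#' df$pc <- c(70, 95, 80, 97, 90, 96)
#' summarize_human_pcs(df)
summarize_human_pcs <- function(per_observer_pcs, observer_col = "observer",
                                pc_col = "pc") {
  df <- as_tibble(per_observer_pcs)
  if (!observer_col %in% names(df)) abort(sprintf("no `%s` column", observer_col))
  if (!pc_col %in% names(df)) abort(sprintf("no `%s` column", pc_col))
  group_cols <- setdiff(names(df), c(observer_col, pc_col))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(n_observers = dplyr::n(),
                     pc_mean = mean(.data[[pc_col]]),
                     pc_se = sd(.data[[pc_col]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  if (any(out$n_observers < 2L)) {
    abort("every category needs at least 2 observers for a confidence interval")
  }
  out |>
    dplyr::mutate(ci95_low = pmax(0, .data$pc_mean - 1.96 * .data$pc_se),
                  ci95_high = pmin(100, .data$pc_mean + 1.96 * .data$pc_se))
}
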