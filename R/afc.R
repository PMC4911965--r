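# M-alternative forced-choice experiments scored as percent correct, plus the
# closed-form PC for Gaussian decision variables used as a validation oracle.

#' Run an M-AFC experiment on decision-variable scores
#'
#' The score-level trial engine that [run_afc()] delegates to. Each trial
#' presents one signal-present score and `m_alternatives - 1` distinct
#' signal-absent scores (sampled without replacement within the trial, with
#' replacement across trials), shuffles the presentation order, and decides
#' for the position with the highest score; ties resolve to the lowest
#' presented position. Signal scores are consumed one full seeded-shuffled
#' pass at a time, so with the default `n_trials = length(lambda_signal)`
#' every signal enters exactly once.
#'
#' @param lambda_signal Numeric vector of signal-present decision variables.
#' @param lambda_noise Numeric vector of signal-absent decision variables
#'   (the shared noise pool).
#' @param m_alternatives Number of alternatives per trial (>= 2; default 4).
#' @param n_trials Number of trials (default one pass over
#'   `lambda_signal`).
#' @param seed Integer seed; identical seeds give identical trial logs.
#' @param signal_ids Optional integer labels recorded for the signal scores
#'   (used by the bootstrap to tag resampled ROIs).
#'
#' @return A list of class `afc_outcome` with `n_trials`, `n_correct`, `pc`
#'   (percent), `m_alternatives`, `seed` and a per-trial `trials` tibble
#'   (signal ROI id, noise ROI ids, lambdas, decision, correct).
#' @export
run_afc_scores <- function(lambda_signal, lambda_noise, m_alternatives = 4L,
                           n_trials = length(lambda_signal), seed = 1L,
                           signal_ids = seq_along(lambda_signal)) {
  m <- assert_count(m_alternatives, "m_alternatives", min = 2L)
  n_trials <- assert_count(n_trials, "n_trials", min = 1L)
  seed <- assert_count(seed, "seed", min = 0L)
  ns <- length(lambda_signal)
  nn <- length(lambda_noise)
  if (ns < 1L) abort("need at least one signal-present score")
  if (nn < m - 1L) {
    abort(sprintf("%d-AFC needs at least %d signal-absent ROIs, got %d", m, m - 1L, nn))
  }
  stopifnot(length(signal_ids) == ns)
  set.seed(seed)
  passes <- ceiling(n_trials / ns)
  sig_seq <- unlist(lapply(seq_len(passes), function(p) sample.int(ns)))[seq_len(n_trials)]

  sig_id_out <- integer(n_trials)
  noise_ids <- matrix(0L, n_trials, m - 1L)
  lam_s <- numeric(n_trials)
  lam_n <- matrix(0, n_trials, m - 1L)
  decision <- integer(n_trials)   # which alternative was chosen; 1 = signal
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    si <- sig_seq[t]
    nid <- sample.int(nn, m - 1L)
    lam <- c(lambda_signal[si], lambda_noise[nid])
    perm <- sample.int(m)               # presented slot i shows alternative perm[i]
    choice <- which.max(lam[perm])      # ties -> lowest presented position
    sig_id_out[t] <- signal_ids[si]
    noise_ids[t, ] <- nid
    lam_s[t] <- lam[1L]
    lam_n[t, ] <- lam[-1L]
    decision[t] <- perm[choice]
    correct[t] <- perm[choice] == 1L
  }
  trials <- tibble(trial = seq_len(n_trials), signal_id = sig_id_out)
  colnames(noise_ids) <- paste0("noise_id_", seq_len(m - 1L))
  colnames(lam_n) <- paste0("lambda_noise_", seq_len(m - 1L))
  trials <- dplyr::bind_cols(trials, as_tibble(noise_ids),
                             tibble(lambda_signal = lam_s), as_tibble(lam_n),
                             tibble(decision = decision, correct = correct))
  structure(list(n_trials = n_trials, n_correct = sum(correct),
                 pc = 100 * mean(correct), m_alternatives = m, seed = seed,
                 trials = trials),
            class = "afc_outcome")
}

#' Run an M-AFC experiment with a trained CHO
#'
#' Computes the decision variable for every ROI in the dataset, then runs
#' seeded forced-choice trials: one signal-present ROI (each used once per
#' shuffled pass) against `m_alternatives - 1` distinct noise ROIs; the
#' highest lambda is called signal-present.
#'
#' @param template A [train_cho()] result.
#' @param bank The matching [build_channel_bank()].
#' @param dataset A [generate_category_dataset()] result (or compatible
#'   `roi_dataset`).
#' @param m_alternatives Alternatives per trial (default 4).
#' @param n_trials Trials (default: number of signal ROIs).
#' @param seed Integer seed.
#'
#' @return An `afc_outcome`; see [run_afc_scores()].
#' @export
run_afc <- function(template, bank, dataset, m_alternatives = 4L,
                    n_trials = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "roi_dataset"))
  lam_s <- decision_variables_stack(dataset$signal, template, bank)
  lam_n <- decision_variables_stack(dataset$noise, template, bank)
  run_afc_scores(lam_s, lam_n, m_alternatives = m_alternatives,
                 n_trials = n_trials %||% length(lam_s), seed = seed)
}

#' @export
print.afc_outcome <- function(x, ...) {
  cat(sprintf("<afc_outcome: %d-AFC, %d/%d correct, PC = %.1f%%>\n",
              x$m_alternatives, x$n_correct, x$n_trials, x$pc))
  invisible(x)
}

#' @rdname run_afc_scores
#' @param x An `afc_outcome`.
#' @param ... Unused.
#' @method tidy afc_outcome
#' @export
tidy.afc_outcome <- function(x, ...) x$trials

#' @rdname run_afc_scores
#' @method glance afc_outcome
#' @export
glance.afc_outcome <- function(x, ...) {
  tibble(n_trials = x$n_trials, n_correct = x$n_correct, pc = x$pc,
         m_alternatives = x$m_alternatives, seed = x$seed)
}

#' Closed-form M-AFC percent correct for Gaussian scores
#'
#' For unit-variance Gaussian decision variables separated by `dprime`, the
#' probability that the signal score exceeds all `m - 1` independent noise
#' scores is `integral phi(x - dprime) * Phi(x)^(m-1) dx`; returned in
#' percent. Used as the analytic oracle for the empirical PC of the trial
#' engine.
#'
#' @param dprime Detectability index (>= 0; vectorised).
#' @param m_alternatives Number of alternatives (>= 2).
#'
#' @return Percent correct, same length as `dprime`.
#' @export
#' @examples
#' pc_closed_form(0, 4)   # 25: chance
#' pc_closed_form(2, 4)
pc_closed_form <- function(dprime, m_alternatives = 4L) {
  m <- assert_count(m_alternatives, "m_alternatives", min = 2L)
  if (any(dprime < 0)) abort("`dprime` must be >= 0")
  vapply(dprime, function(d) {
    100 * integrate(function(x) dnorm(x - d) * pnorm(x)^(m - 1L),
                    -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1L))
}
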