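# CHO training, the decision variable and the detectability index.

test_that("training on identical classes gives a zero template", {
  ds <- tiny_dataset()
  tmpl <- train_cho(ds$noise[, , 1:30], ds$noise[, , 1:30], tiny_bank)
  expect_equal(tmpl$w, rep(0, tiny_nch), tolerance = 1e-12)
  expect_equal(detectability_index(tmpl), 0, tolerance = 1e-8)
})

test_that("the linear solve matches an explicit matrix-inversion oracle", {
  for (seed in c(2L, 17L, 301L)) {
    ds <- tiny_dataset(seed = seed)
    tmpl <- train_cho(ds$signal, ds$noise, tiny_bank)
    s_bar <- 0.5 * (tmpl$cov_signal_c + tmpl$cov_noise_c)
    w_ref <- drop(solve(s_bar) %*% (tmpl$mean_signal_c - tmpl$mean_noise_c))
    expect_equal(tmpl$w, w_ref, tolerance = 1e-8)
  }
})

test_that("training stats are the sample moments of the channel outputs", {
  ds <- tiny_dataset(seed = 5L)
  tmpl <- train_cho(ds$signal, ds$noise, tiny_bank)
  gs <- sapply(seq_len(30), function(k) apply_channels(ds$signal[, , k], tiny_bank))
  expect_equal(tmpl$mean_signal_c, rowMeans(gs), tolerance = 1e-10)
  expect_equal(tmpl$cov_signal_c, cov(t(gs)), tolerance = 1e-10)
  expect_equal(tmpl$cov_signal_c, t(tmpl$cov_signal_c))  # symmetry
  expect_true(all(eigen(0.5 * (tmpl$cov_signal_c + tmpl$cov_noise_c),
                        symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  expect_error(train_cho(ds$signal[, , 1, drop = FALSE], ds$noise, tiny_bank),
               "at least 2")
})

test_that("channel-space covariance equals the image-space route", {
  # the 10x10 covariance of channel outputs must equal U^T K U with K the
  # image-space sample covariance (the two algebraically identical routes)
  side <- 41L
  bank41 <- build_channel_bank(side)
  ds <- generate_category_dataset(category(15, 1L, 10, 6),
                                  noise_model("white", 8),
                                  n_signal = 20, n_noise = 20, seed = 21L)
  X <- matrix(ds$signal, side * side, 20)
  K_img <- cov(t(X))
  K_route <- t(bank41$U) %*% K_img %*% bank41$U
  G <- t(bank41$U) %*% X
  K_direct <- cov(t(G))
  expect_equal(K_direct, K_route, tolerance = 1e-6 * max(abs(K_route)))
})

test_that("decision variable is affine-invariant and matches the mean identity", {
  ds <- tiny_dataset(seed = 8L)
  tmpl <- train_cho(ds$signal, ds$noise, tiny_bank)
  roi <- ds$signal[, , 3]
  expect_equal(decision_variable(roi + 100, tmpl, tiny_bank),
               decision_variable(roi, tmpl, tiny_bank), tolerance = 1e-8)
  expect_equal(decision_variable(matrix(3, tiny_side, tiny_side), tmpl, tiny_bank),
               0, tolerance = 1e-10)

  zero_tmpl <- tmpl
  zero_tmpl$w <- rep(0, tiny_nch)
  expect_equal(decision_variable(roi, zero_tmpl, tiny_bank), 0)

  lam_s <- sapply(seq_len(30), function(k) decision_variable(ds$signal[, , k], tmpl, tiny_bank))
  lam_n <- sapply(seq_len(120), function(k) decision_variable(ds$noise[, , k], tmpl, tiny_bank))
  expect_equal(mean(lam_s) - mean(lam_n),
               sum(tmpl$w * (tmpl$mean_signal_c - tmpl$mean_noise_c)),
               tolerance = 1e-8)
})

test_that("scale invariance: rescaling the data rescales w and preserves decisions", {
  ds <- tiny_dataset(seed = 13L)
  tmpl1 <- train_cho(ds$signal, ds$noise, tiny_bank)
  k <- 7.3
  tmpl2 <- train_cho(ds$signal * k, ds$noise * k, tiny_bank)
  expect_equal(tmpl2$w, tmpl1$w / k, tolerance = 1e-6)

  out1 <- run_afc(tmpl1, tiny_bank, ds, seed = 99L)
  ds_k <- ds
  ds_k$signal <- ds$signal * k
  ds_k$noise <- ds$noise * k
  out2 <- run_afc(tmpl2, tiny_bank, ds_k, seed = 99L)
  expect_identical(out1$trials$correct, out2$trials$correct)
})

test_that("detectability index: norm case and Monte-Carlo agreement", {
  # identity covariance, mean difference (3, 4, 0, ...) -> d' = 5
  tmpl <- structure(list(w = rep(0, 10),
                         mean_signal_c = c(3, 4, rep(0, 8)),
                         mean_noise_c = rep(0, 10),
                         cov_signal_c = diag(10), cov_noise_c = diag(10),
                         n_train_signal = 10L, n_train_noise = 10L, ridge = 0),
                    class = "cho_template")
  expect_equal(detectability_index(tmpl), 5)

  # sampling oracle: d' vs (mean lambda_s - mean lambda_n) / pooled SD on
  # Gaussian channel outputs drawn from the trained moments
  ds <- tiny_dataset(seed = 30L, n_signal = 60L)
  tr <- train_cho(ds$signal, ds$noise, tiny_bank)
  s_bar <- 0.5 * (tr$cov_signal_c + tr$cov_noise_c)
  w <- solve(s_bar, tr$mean_signal_c - tr$mean_noise_c)
  set.seed(77)
  L <- chol(s_bar)
  n_mc <- 1e5L
  z_s <- matrix(rnorm(n_mc * tiny_nch), n_mc) %*% L
  z_n <- matrix(rnorm(n_mc * tiny_nch), n_mc) %*% L
  lam_s <- drop(z_s %*% w) + sum(w * tr$mean_signal_c)
  lam_n <- drop(z_n %*% w) + sum(w * tr$mean_noise_c)
  d_mc <- (mean(lam_s) - mean(lam_n)) / sqrt(0.5 * (var(lam_s) + var(lam_n)))
  expect_equal(detectability_index(tr), d_mc, tolerance = 0.02)
})

test_that("PC rises monotonically along a contrast ladder", {
  pcs <- vapply(c(2, 4, 8, 16), function(con) {
    ds <- tiny_dataset(contrast = con, sigma = 6, n_signal = 50L,
                       n_noise = 200L, seed = 44L)
    tmpl <- train_cho(ds$signal, ds$noise, tiny_bank)
    run_afc(tmpl, tiny_bank, ds, n_trials = 200L, seed = 45L)$pc
  }, numeric(1))
  expect_true(all(diff(pcs) >= 0))
  expect_gt(pcs[4], pcs[1])
})
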