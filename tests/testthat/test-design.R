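test_that("empty event tables give an intercept-only design", {
  empty <- simulate_testing_design(0, 0, seed = 1)
  des <- build_trial_design(empty, n_scans = 10, tr = 2.5)
  expect_equal(colnames(des$X), "intercept")
  nuis <- matrix(rnorm(20), 10, 2)
  des2 <- build_trial_design(empty, 10, 2.5, nuisance = nuis)
  expect_equal(ncol(des2$X), 3)
})

test_that("a trial regressor peaks where the dense convolution oracle peaks", {
  ev <- event_table(data.frame(onset = 0, duration = 4, event_kind = "picture",
                               condition = "Rc", item_id = 1L))
  des <- build_trial_design(ev, n_scans = 60, tr = 0.5, include_pause = FALSE,
                            intercept = FALSE)
  scan_t <- (0:59) * 0.5
  oracle <- dense_boxcar_response(0, 4, hrf_params(), scan_t)
  expect_equal(which.max(des$X[, 1]), which.max(oracle))
  # whole shape agrees with the oracle up to the shared normalization
  o <- oracle / hrf_peak_value_test()
  expect_lt(max(abs(des$X[, 1] - o)), 5e-3 * max(o))
})

test_that("well-separated trials have disjoint support", {
  ev <- event_table(data.frame(onset = c(0, 60), duration = 4,
                               event_kind = "picture", condition = c("Rc", "Nr"),
                               item_id = 1:2))
  des <- build_trial_design(ev, n_scans = 50, tr = 2.5, include_pause = FALSE,
                            intercept = FALSE)
  expect_equal(sum(abs(des$X[, 1]) > 0 & abs(des$X[, 2]) > 0), 0)
})

test_that("events outside the run are rejected", {
  ev <- event_table(data.frame(onset = 100, duration = 4, event_kind = "picture",
                               condition = "Rc", item_id = 1L))
  expect_error(build_trial_design(ev, n_scans = 10, tr = 2.5), "outside")
})

test_that("OLS recovers known coefficients exactly and matches the normal equations", {
  sub <- make_tiny_subject(seed = 2, noise_sd = 0)
  fit <- fit_trial_betas(sub$sim, sub$design)
  amps <- sub$sim$amplitudes[rownames(fit$betas), , drop = FALSE]
  expect_lt(max(abs(fit$betas - amps) / pmax(abs(amps), 1e-12)), 1e-8)

  # noisy case: OLS equals an independent normal-equations solve
  subn <- make_tiny_subject(seed = 3, noise_sd = 0.5)
  fitn <- fit_trial_betas(subn$sim, subn$design)
  X <- subn$design$X
  oracle <- solve(crossprod(X), crossprod(X, subn$sim$signal))
  expect_lt(max(abs(fitn$betas - oracle[rownames(fitn$betas), ])), 1e-8)
})

test_that("intercept-only signals yield zero trial betas", {
  sub <- make_tiny_subject(seed = 4, noise_sd = 0)
  sig <- matrix(3.7, nrow(sub$sim$signal), ncol(sub$sim$signal),
                dimnames = dimnames(sub$sim$signal))
  fit <- fit_trial_betas(sig, sub$design)
  expect_lt(max(abs(fit$betas)), 1e-8)
  expect_equal(unname(fit$other["intercept", 1]), 3.7, tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  sub <- make_tiny_subject(seed = 5, noise_sd = 0)
  dup <- sub$design
  dup$X <- cbind(dup$X, bad_copy = dup$X[, dup$trial_info$column[1]])
  expect_error(fit_trial_betas(sub$sim, dup), "bad_copy")
})

test_that("LS-S recovers homogeneous amplitudes and tracks LS-A", {
  # with per-trial amplitude spread, LS-S is biased by construction (the
  # pooled-other regressors cannot absorb trial heterogeneity), so exactness
  # is only expected for homogeneous amplitudes
  ev <- simulate_testing_design(4, 2, conditions = c("Rc", "Nr"), seed = 6)
  labs <- paste0("roi", 1:6)
  ps <- planted_structure(roi_labels = labs, n_blocks = 2,
                          within_block_corr = c(Rc = 0, Nr = 0),
                          between_block_corr = c(Rc = 0, Nr = 0), amp_sd = 1e-12)
  sim <- simulate_bold(ev, ps, noise_sd = 0, amp_mean = 1.3, seed = 7)
  des <- build_trial_design(ev, nrow(sim$signal), 2.5)
  fit_s <- fit_trial_betas(sim, des, mode = "lss")
  expect_lt(max(abs(fit_s$betas - 1.3)), 1e-6)

  subn <- make_tiny_subject(seed = 6, noise_sd = 0)
  fit_a <- fit_trial_betas(subn$sim, subn$design, mode = "lsa")
  fit_s2 <- fit_trial_betas(subn$sim, subn$design, mode = "lss")
  expect_gt(cor(as.vector(fit_a$betas), as.vector(fit_s2$betas)), 0.9)
})

test_that("round trip: planted amplitudes recovered across seeds, RMSE shrinks with noise", {
  rmse <- sapply(c(2, 0.5, 0), function(ns) {
    sub <- make_tiny_subject(seed = 8, noise_sd = ns)
    fit <- fit_trial_betas(sub$sim, sub$design)
    amps <- sub$sim$amplitudes[rownames(fit$betas), , drop = FALSE]
    sqrt(mean((fit$betas - amps)^2))
  })
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 1e-8)
})
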