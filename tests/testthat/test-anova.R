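test_that("retention is the testing minus training difference", {
  expect_equal(retention(12, 9), 3L)
  expect_equal(retention(9, 9), 0L)
  expect_equal(retention(5, 9), -4L)
  expect_error(retention(-1, 3), "non-negative")
})

test_that("constant data give zero F for every effect", {
  tab <- make_retention(sd = 0)
  tab$retention <- 0L
  an <- mixed_rm_anova(tab)
  expect_true(all(an$effects$F == 0))
  expect_true(all(an$effects$p == 1))
})

test_that("mixed ANOVA F statistics match the direct sums-of-squares oracle", {
  eff <- matrix(c(1, 0.5, -1, 0.2, -0.4, -1.5), 2, 3,
                dimnames = list(c("day5", "day15"), c("Rc", "Rw", "Nr")))
  tab <- make_retention(n_per_group = 12, effects = eff, sd = 1.5, seed = 42)
  an <- mixed_rm_anova(tab)
  oracle <- ss_oracle(tab)
  expect_equal(an$effects$F[an$effects$effect == "group"], oracle$F_group,
               tolerance = 1e-8)
  expect_equal(an$effects$F[an$effects$effect == "condition"], oracle$F_cond,
               tolerance = 1e-8)
  expect_equal(an$effects$F[an$effects$effect == "group:condition"], oracle$F_int,
               tolerance = 1e-8)
  expect_true(all(an$effects$eta_p2 >= 0 & an$effects$eta_p2 <= 1))
})

test_that("F statistics are invariant to adding a constant", {
  tab <- make_retention(effects = matrix(c(2, 0, -2, 1, 0, -1), 2, 3,
                        dimnames = list(c("day5", "day15"), c("Rc", "Rw", "Nr"))),
                        seed = 3)
  an1 <- mixed_rm_anova(tab)
  tab2 <- tab; tab2$retention <- tab2$retention + 7L
  an2 <- mixed_rm_anova(tab2, value = "retention")
  expect_equal(an1$effects$F, an2$effects$F, tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon: bounds, sphericity and eigen oracle", {
  cs <- matrix(0.3, 3, 3); diag(cs) <- 1     # compound symmetry
  expect_equal(gg_epsilon(cs), 1)

  # rank-one within-contrast covariance: maximal non-sphericity, k = 3
  v <- c(1, -1, 0)
  S1 <- tcrossprod(v) + 1e-9 * diag(3)
  expect_equal(gg_epsilon(S1), 0.5, tolerance = 1e-4)

  set.seed(11)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A)
    k <- 3
    H <- diag(k) - 1 / k                     # centering
    Sc <- H %*% S %*% H
    lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values[1:(k - 1)]
    eps_eigen <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(gg_epsilon(S), min(1, max(1 / (k - 1), eps_eigen)),
                 tolerance = 1e-10)
  }
})

test_that("spherical data leave the correction off; epsilon within bounds", {
  tab <- make_retention(n_per_group = 14, sd = 1, seed = 8)
  an <- mixed_rm_anova(tab)
  expect_gte(an$epsilon, 0.5)
  expect_lte(an$epsilon, 1)
  expect_false(an$corrected)   # exchangeable noise: sphericity holds
  expect_true(all(is.finite(an$effects$p_gg[an$effects$effect != "group"])))
})

test_that("Bonferroni post-hocs multiply and cap p-values", {
  df <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), 3),
                   condition = rep(c("A", "B", "C"), each = 10),
                   retention = c(rnorm(10, 2), rnorm(10, 0), rnorm(10, 0)))
  ph <- bonferroni_posthoc(df)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p))
  same <- data.frame(subject_id = rep(sprintf("s%02d", 1:6), 2),
                     condition = rep(c("A", "B"), each = 6),
                     retention = rep(1:6, 2))
  expect_equal(bonferroni_posthoc(same)$p_adj, 1)
})

test_that("per-region one-way ANOVA matches its oracle and rejects degenerate input", {
  set.seed(21)
  n <- 12
  d <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                   condition = c("Rc", "Rw", "Nr"), stringsAsFactors = FALSE)
  d$region <- "hippocampus"
  d$beta <- rnorm(nrow(d), 0.3) + ifelse(d$condition == "Rw", 0.8, 0)
  ra <- roi_rm_anova(d)
  # one-way RM oracle: condition SS over (subject x condition) residual SS
  y <- d$beta
  m_c <- tapply(y, d$condition, mean); m_s <- tapply(y, d$subject_id, mean)
  mu <- mean(y)
  ss_c <- n * sum((m_c - mu)^2)
  ss_s <- 3 * sum((m_s - mu)^2)
  ss_e <- sum((y - mu)^2) - ss_c - ss_s
  F_oracle <- (ss_c / 2) / (ss_e / (2 * (n - 1)))
  expect_equal(ra$effects$F, F_oracle, tolerance = 1e-8)
  expect_equal(ra$effects$df_den, 2 * (n - 1))

  d0 <- d; d0$beta <- ave(d0$beta, d0$subject_id)   # identical across conditions
  expect_equal(roi_rm_anova(d0)$effects$F, 0)

  single <- d[d$subject_id == "s01", ]
  expect_error(roi_rm_anova(single), "at least 2 subjects")

  rb <- roi_rm_anova(d, error = "between")
  expect_equal(rb$effects$df_den, 3 * n - 3)
})

test_that("default cohort effect sizes reproduce the qualitative post-hoc pattern", {
  b5 <- simulate_behavior(14, group = "day5", seed = 101)
  b15 <- simulate_behavior(13, condition_means = c(Rc = 8.4, Rw = 5.4, Nr = 2.4),
                           group = "day15", seed = 102)
  tab <- retention_table(rbind(as.data.frame(b5), as.data.frame(b15)))
  an <- mixed_rm_anova(tab)
  expect_lt(an$effects$p_reported[an$effects$effect == "condition"], 0.001)
  ph5 <- an$posthoc$day5; ph15 <- an$posthoc$day15
  get_p <- function(ph, a, b)
    ph$p_adj[ph$pair %in% c(paste(a, "vs", b), paste(b, "vs", a))]
  expect_gt(get_p(ph5, "Rc", "Rw"), 0.05)   # early test: Rc vs Rw indistinct
  expect_lt(get_p(ph5, "Rc", "Nr"), 0.05)
  expect_lt(get_p(ph5, "Rw", "Nr"), 0.05)
  expect_true(all(ph15$p_adj < 0.05))       # delayed test separates all pairs
})
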