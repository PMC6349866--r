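test_that("pearson matrix reproduces hand-computed correlations", {
  s <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  m <- pearson_matrix(s)
  expect_equal(m["a", "b"], 0.8)          # cov 4 over sd product 5
  expect_equal(m["a", "c"], -1)
  expect_true(is.na(m["a", "a"]))
  s2 <- cbind(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(pearson_matrix(s2)["x", "y"], 1)
})

test_that("zero-variance regions become NA with a warning; too few trials error", {
  s <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = c(2, 1, 4, 3))
  expect_warning(m <- pearson_matrix(s), "zero-variance")
  expect_true(all(is.na(m["b", ])))
  expect_false(is.na(m["a", "c"]))
  expect_error(pearson_matrix(cbind(a = 1:2, b = 2:1)), "3 trials")
})

test_that("fisher transform is the clipped arctanh", {
  r <- matrix(c(NA, 0, 0.5, -0.5, 0, NA, 1, -1, 0.5, 1, NA, 0.25,
                -0.5, -1, 0.25, NA), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  m <- connectivity_matrix(r, scale = "r")
  z <- fisher_z(m)
  expect_equal(z["a", "b"], 0)
  expect_equal(z["a", "c"], log(3) / 2)    # arctanh(0.5)
  expect_equal(z["a", "c"], -z["a", "d"])  # odd symmetry
  expect_true(is.finite(z["b", "c"]))      # |r| = 1 clipped, stays finite
  expect_error(fisher_z(z), "r scale")
})

test_that("fisher_z inverts tanh within 1e-12 for |z| <= 5", {
  zs <- seq(-5, 5, length.out = 21)
  n <- length(zs) + 1
  zm <- matrix(0, n, n); zm[1, -1] <- zs; zm <- zm + t(zm)
  dimnames(zm) <- list(paste0("r", 1:n), paste0("r", 1:n))
  rm_ <- connectivity_matrix(tanh(zm), scale = "r")
  back <- fisher_z(rm_, clip_eps = 1e-15)
  expect_lt(max(abs(back[1, -1] - zs)), 1e-12)
})

test_that("grand mean averages elementwise with pairwise NA exclusion", {
  mk <- function(v) {
    m <- matrix(v, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    diag(m) <- NA
    connectivity_matrix(m, scale = "z", condition = "Rc")
  }
  one <- grand_mean_matrix(list(mk(0.2)))
  expect_equal(one["a", "b"], 0.2)
  two <- grand_mean_matrix(list(mk(0.2), mk(0.4)))
  expect_equal(two["a", "b"], 0.3)
  expect_equal(attr(two, "n_subjects"), 2L)

  m3 <- mk(0.6); m3["a", "b"] <- m3["b", "a"] <- NA
  mixed <- grand_mean_matrix(list(mk(0.2), m3))
  expect_equal(mixed["a", "b"], 0.2)        # pairwise exclusion
  expect_equal(attr(mixed, "n_used")["a", "b"], 1)
  expect_equal(mixed["a", "c"], 0.4)
  expect_error(grand_mean_matrix(list()), "empty")
})

test_that("matrices are exactly symmetric and permutation-equivariant", {
  sub <- make_tiny_subject(seed = 9, noise_sd = 0.3)
  fit <- fit_trial_betas(sub$sim, sub$design)
  m <- pearson_matrix(fit, "Rc")
  expect_equal(max(abs(unclass(m) - t(unclass(m))), na.rm = TRUE), 0)
  perm <- rev(rownames(m))
  m_perm <- pearson_matrix(condition_betas(fit, "Rc")[, perm])
  expect_equal(as.numeric(m_perm), as.numeric(unclass(m)[perm, perm]))
  expect_equal(rownames(m_perm), perm)
})

test_that("grand-mean z recovers the planted within-block correlation", {
  # 6 subjects, 60 trials of one condition, blocks of 6 regions
  labs <- paste0("r", 1:12)
  ps <- planted_structure(roi_labels = labs, n_blocks = 2,
                          within_block_corr = c(Rc = 0.6),
                          between_block_corr = c(Rc = 0.1))
  zs <- lapply(1:6, function(s) {
    ev <- simulate_testing_design(60, 0, conditions = "Rc", seed = 100 + s)
    sim <- simulate_bold(ev, ps, noise_sd = 0, seed = 200 + s)
    fisher_z(pearson_matrix(sim$amplitudes))
  })
  gm <- grand_mean_matrix(zs)
  blk <- unclass(gm)[1:6, 1:6]
  within_z <- mean(blk[upper.tri(blk)])
  expect_lt(abs(within_z - atanh(0.6)), 0.08)
})

test_that("connectivity matrices round-trip through TSV with sidecar", {
  sub <- make_tiny_subject(seed = 10, noise_sd = 0.2)
  fit <- fit_trial_betas(sub$sim, sub$design)
  gm <- grand_mean_matrix(list(fisher_z(pearson_matrix(fit, "Rc"))))
  path <- tempfile(fileext = ".tsv")
  write_connectivity_matrix(gm, path)
  back <- read_connectivity_matrix(path)
  expect_equal(as.numeric(back), as.numeric(gm), tolerance = 1e-6)
  expect_equal(dimnames(back), dimnames(gm))
  expect_equal(attr(back, "scale"), "z")
  expect_equal(attr(back, "condition"), "Rc")
})
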