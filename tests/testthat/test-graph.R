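test_that("binarization keeps ties and drops isolated regions", {
  m2 <- matrix(c(NA, 0.4, 0.4, NA), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- binarize(m2, 0.35)
  expect_equal(sum(g$adjacency) / 2, 1)
  expect_equal(g$nodes, c("a", "b"))
  g2 <- binarize(m2, 0.5)
  expect_equal(sum(g2$adjacency), 0)
  expect_length(g2$nodes, 0)
  g3 <- binarize(m2, 0.4)      # threshold equal to the entry: edge included
  expect_equal(sum(g3$adjacency) / 2, 1)
})

test_that("degree and clustering match hand-computed small graphs", {
  path <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(average_degree(path), 4 / 3)
  expect_equal(clustering_coefficient(path), 0)

  k5 <- matrix(1L, 5, 5); diag(k5) <- 0L
  expect_equal(average_degree(k5), 4)
  expect_equal(clustering_coefficient(k5), 1)

  tri <- adjacency_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clustering_coefficient(tri), 1)

  k4_minus <- matrix(1L, 4, 4); diag(k4_minus) <- 0L
  k4_minus[1, 2] <- k4_minus[2, 1] <- 0L
  expect_equal(clustering_coefficient(k4_minus), 5 / 6)
  expect_equal(average_degree(k4_minus), (2 + 2 + 3 + 3) / 4)
})

test_that("graph metrics equal brute-force enumeration and igraph on random graphs", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.8))
    expect_equal(average_degree(a), bf_average_degree(a))
    expect_equal(clustering_coefficient(a), bf_clustering(a))
    if (any(rowSums(a) > 0)) {
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      loc <- igraph::transitivity(g, type = "local", isolates = "zero")
      expect_equal(clustering_coefficient(a), mean(loc[rowSums(a) > 0]))
    }
  }
})

test_that("threshold sweep obeys its grid and monotonicity contracts", {
  set.seed(7)
  z <- matrix(rnorm(30 * 30, 0.2, 0.15), 30, 30)
  z <- (z + t(z)) / 2; diag(z) <- NA
  dimnames(z) <- list(paste0("r", 1:30), paste0("r", 1:30))
  m <- connectivity_matrix(z, scale = "z")
  sw <- threshold_sweep(m, t_max = 0.6, count = 500)
  expect_equal(nrow(sw), 500)
  expect_equal(sw$threshold[1], min(z[upper.tri(z)], na.rm = TRUE))
  expect_equal(sw$threshold[500], 0.6)
  expect_true(all(diff(sw$n_links) <= 0))
  # mean degree is non-increasing wherever the node set is stable (it can
  # only bump up when isolated nodes leave the average)
  stable <- diff(sw$n_nodes) == 0
  expect_true(all(diff(sw$k_mean)[stable] <= 1e-12))
  expect_true(all(abs(sw$n_links - sw$n_nodes * sw$k_mean / 2) < 1e-9))
  # at the grid minimum every pair is linked
  expect_equal(sw$n_links[1], sum(z[upper.tri(z)] >= sw$threshold[1], na.rm = TRUE))
  expect_error(threshold_sweep(m, t_max = -10), "below the minimum")
})

test_that("matched ER null fixes the edge count; probability mode matches E[C] = p", {
  null_m <- er_null(20, 40, replicates = 50, mode = "matched", seed = 1)
  expect_true(all(null_m$n_edges == 40))
  expect_true(all(null_m$clustering >= 0 & null_m$clustering <= 1))

  full <- er_null(6, 15, replicates = 10, mode = "matched", seed = 2)
  expect_true(all(full$clustering == 1))        # complete graphs

  expect_error(er_null(5, 11, mode = "matched"), "exceeds")

  null_p <- er_null(40, replicates = 200, mode = "probability", p = 0.3, seed = 3)
  expect_lt(abs(mean(null_p$clustering) - 0.3), 0.02)
})

test_that("Monte-Carlo p-values follow the add-one convention", {
  null <- structure(list(clustering = seq(0.1, 0.9, length.out = 1000)),
                    class = "er_null")
  expect_equal(null_pvalue(0.05, null), 1)               # below all draws
  expect_equal(null_pvalue(0.95, null), 1 / 1001)        # above all draws
  one <- structure(list(clustering = 0.5), class = "er_null")
  expect_equal(null_pvalue(0.5, one), 1)                 # tie counts as >=
  expect_error(null_pvalue(0.5, structure(list(clustering = numeric(0)),
                                          class = "er_null")), "empty")
})

test_that("adjacency export masks, reorders and summarizes correctly", {
  n <- 90
  m <- matrix(0.4, n, n); diag(m) <- NA
  dimnames(m) <- list(paste0("r", 1:n), paste0("r", 1:n))
  cm <- connectivity_matrix(m, scale = "z")
  exp1 <- adjacency_export(cm, 0.35)
  expect_equal(exp1$k_mean, 89)
  expect_equal(exp1$clustering, 1)

  low <- connectivity_matrix(matrix(0.1, 4, 4,
           dimnames = list(letters[1:4], letters[1:4])), scale = "z")
  expect_equal(sum(adjacency_export(low, 0.35)$adjacency), 0)

  set.seed(9)
  r10 <- matrix(runif(100, 0, 0.7), 10, 10)
  r10 <- (r10 + t(r10)) / 2; diag(r10) <- NA
  dimnames(r10) <- list(paste0("n", 1:10), paste0("n", 1:10))
  cm10 <- connectivity_matrix(r10, scale = "z")
  ex <- adjacency_export(cm10, 0.35)
  mask <- ifelse(!is.na(r10) & r10 >= 0.35, 1L, 0L)
  expect_equal(unname(ex$adjacency), unname(mask))
  ord <- rev(rownames(r10))
  ex2 <- adjacency_export(cm10, 0.35, roi_order = ord)
  expect_equal(rownames(ex2$adjacency), ord)
  expect_error(adjacency_export(cm10, 0.35, roi_order = ord[-1]), "permutation")
})

test_that("sweep nulls flag planted community structure as non-random", {
  labs <- paste0("r", 1:12)
  ps <- planted_structure(roi_labels = labs, n_blocks = 2,
                          within_block_corr = c(Rc = 0.7),
                          between_block_corr = c(Rc = 0.05))
  zs <- lapply(1:4, function(s) {
    ev <- simulate_testing_design(40, 0, conditions = "Rc", seed = 300 + s)
    sim <- simulate_bold(ev, ps, noise_sd = 0, seed = 400 + s)
    fisher_z(pearson_matrix(sim$amplitudes))
  })
  gm <- grand_mean_matrix(zs)
  sw <- threshold_sweep(gm, t_max = 0.6, count = 60, null_reps = 200, seed = 5)
  mid <- sw[sw$threshold > 0.3 & sw$threshold < 0.6, ]
  expect_true(all(mid$clustering > mid$null_c_mean))
  expect_true(any(mid$significant))
})
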