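# Independent brute-force oracles and small fixture builders.

# mean degree by explicit per-node tally over non-isolated nodes
bf_average_degree <- function(a) {
  n <- nrow(a)
  deg <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && a[i, j] == 1)
    deg[i] <- deg[i] + 1L
  deg <- deg[deg > 0]
  if (!length(deg)) 0 else sum(deg) / length(deg)
}

# global clustering by explicit neighbor-pair enumeration
bf_clustering <- function(a) {
  n <- nrow(a)
  local <- numeric(n)
  listed <- logical(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1 & seq_len(n) != i)
    listed[i] <- length(nb) > 0
    if (length(nb) < 2) { local[i] <- 0; next }
    linked <- 0L; total <- 0L
    for (u in seq_along(nb)) for (v in seq_along(nb)) if (u < v) {
      total <- total + 1L
      if (a[nb[u], nb[v]] == 1) linked <- linked + 1L
    }
    local[i] <- linked / total
  }
  if (!any(listed)) 0 else mean(local[listed])
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  a + t(a)
}

adjacency_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1L; a[e[2], e[1]] <- 1L }
  a
}

# dense-grid numeric convolution of a boxcar with the double-gamma kernel,
# independent of the package's regressor builder
dense_boxcar_response <- function(onset, duration, params, t_eval, dt = 0.001) {
  tt <- seq(0, params$kernel_length + duration, by = dt)
  h <- stats::dgamma(tt, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    stats::dgamma(tt, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) / params$peak_undershoot_ratio
  resp <- vapply(t_eval - onset, function(u) {
    if (u <= 0) return(0)
    s <- seq(0, min(u, duration), by = dt)
    sum(stats::approx(tt, h, xout = u - s, yleft = 0, yright = 0)$y) * dt
  }, numeric(1))
  resp
}

# dense-grid peak of the double-gamma, independent of the package's optimizer
hrf_peak_value_test <- function(params = hrf_params(), dt = 1e-4) {
  tt <- seq(0, params$kernel_length, by = dt)
  max(stats::dgamma(tt, shape = params$peak_delay / params$peak_dispersion,
                    scale = params$peak_dispersion) -
      stats::dgamma(tt, shape = params$undershoot_delay / params$undershoot_dispersion,
                    scale = params$undershoot_dispersion) / params$peak_undershoot_ratio)
}

make_retention <- function(n_per_group = 12, effects = NULL, sd = 1, seed = 1) {
  # balanced 2-group x 3-condition table with additive planted effects
  set.seed(seed)
  conds <- c("Rc", "Rw", "Nr")
  groups <- c("day5", "day15")
  if (is.null(effects))
    effects <- matrix(0, 2, 3, dimnames = list(groups, conds))
  df <- expand.grid(condition = conds,
                    subject_id = sprintf("s%03d", seq_len(2 * n_per_group)),
                    stringsAsFactors = FALSE)[, 2:1]
  df$group <- rep(groups, each = 3 * n_per_group)[seq_len(nrow(df))]
  df$correct_training <- 9L
  raw <- 9 + effects[cbind(df$group, df$condition)] + rnorm(nrow(df), 0, sd)
  df$correct_testing <- pmin(12L, pmax(0L, as.integer(round(raw))))
  retention_table(df)
}

# direct sums-of-squares decomposition for the balanced mixed design
ss_oracle <- function(tab) {
  y <- tab$retention
  subj <- factor(tab$subject_id); cond <- factor(tab$condition)
  grp <- factor(tab$group)
  k <- nlevels(cond); n <- nlevels(subj)
  mu <- mean(y)
  m_g <- tapply(y, grp, mean); n_g <- table(grp) / k
  m_c <- tapply(y, cond, mean)
  m_gc <- tapply(y, list(grp, cond), mean)
  m_s <- tapply(y, subj, mean)
  g_of_s <- tapply(as.character(tab$group), subj, `[`, 1)

  ss_group <- k * sum(n_g * (m_g - mu)^2)
  ss_subj_within <- k * sum((m_s - m_g[g_of_s])^2)
  ss_cond <- n * sum((m_c - mu)^2)
  ss_int <- 0
  for (g in levels(grp)) for (cc in levels(cond))
    ss_int <- ss_int + n_g[[g]] * (m_gc[g, cc] - m_g[[g]] - m_c[[cc]] + mu)^2
  ss_tot <- sum((y - mu)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj_within - ss_cond - ss_int

  df_group <- nlevels(grp) - 1
  df_subj <- n - nlevels(grp)
  df_cond <- k - 1
  df_int <- df_group * df_cond
  df_err <- df_subj * df_cond
  list(F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
       F_cond = (ss_cond / df_cond) / (ss_err_within / df_err),
       F_int = (ss_int / df_int) / (ss_err_within / df_err))
}

# small noiseless subject used by several GLM / connectivity tests
make_tiny_subject <- function(seed = 1, noise_sd = 0, n_items = 4, n_fillers = 2,
                              conditions = c("Rc", "Nr")) {
  ev <- simulate_testing_design(n_items, n_fillers, conditions = conditions,
                                seed = seed)
  labs <- paste0("roi", sprintf("%02d", 1:12))
  w <- stats::setNames(rep(0.6, length(conditions)), conditions)
  b <- stats::setNames(rep(0.2, length(conditions)), conditions)
  ps <- planted_structure(roi_labels = labs, n_blocks = 2,
                          within_block_corr = w, between_block_corr = b)
  sim <- simulate_bold(ev, ps, noise_sd = noise_sd, seed = seed + 1)
  des <- build_trial_design(ev, nrow(sim$signal), 2.5)
  list(events = ev, planted = ps, sim = sim, design = des)
}
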