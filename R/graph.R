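#' Binarize a grand-mean matrix into an unweighted graph
#'
#' Regions i and j are linked iff their grand-mean association is greater
#' than or equal to `threshold` (ties included).  Nodes are the regions
#' with a nonzero number of links; isolated regions are excluded from the
#' node list (and hence from degree and clustering averages).
#'
#' @param m A `connectivity_matrix` (z-scale grand mean in the standard
#'   pipeline) or a plain symmetric matrix.
#' @param threshold Binarization threshold.
#' @return Object of class `binary_graph`: list with `adjacency` (full 0/1
#'   matrix over all regions, labeled), `nodes` (labels with degree >= 1),
#'   `threshold`.
#' @export
binarize <- function(m, threshold) {
  a <- unclass(m)
  a <- ifelse(!is.na(a) & a >= threshold, 1L, 0L)
  diag(a) <- 0L
  deg <- rowSums(a)
  labs <- rownames(a)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(a)))
  dimnames(a) <- list(labs, labs)
  structure(list(adjacency = a, nodes = labs[deg > 0], threshold = threshold),
            class = "binary_graph")
}

as_adjacency <- function(graph) {
  if (inherits(graph, "binary_graph")) graph$adjacency
  else as.matrix(graph)
}

#' Average degree of a binary graph
#'
#' Mean number of links per node, averaged over the nodes with at least one
#' link; 0 for an empty graph.
#'
#' @param graph A `binary_graph` (or a 0/1 adjacency matrix).
#' @return The average degree, a single number.
#' @export
average_degree <- function(graph) {
  a <- as_adjacency(graph)
  deg <- rowSums(a)
  deg <- deg[deg > 0]
  if (!length(deg)) return(0)
  mean(deg)
}

#' Global clustering coefficient of a binary graph
#'
#' Local clustering of node i is the fraction of its neighbor pairs that
#' are themselves linked (`2 t_i / (k_i (k_i - 1))`, with `t_i` the number
#' of triangles through i); nodes of degree < 2 have local clustering 0.
#' The global coefficient is the mean of the local values over the nodes
#' with at least one link; 0 for an empty graph.
#'
#' @inheritParams average_degree
#' @return The clustering coefficient, in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  a <- as_adjacency(graph)
  deg <- rowSums(a)
  keep <- deg > 0
  if (!any(keep)) return(0)
  tri2 <- rowSums((a %*% a) * a)      # 2 x number of triangles through i
  local <- ifelse(deg >= 2, tri2 / (deg * (deg - 1)), 0)
  mean(local[keep])
}

#' Threshold sweep of a grand-mean matrix
#'
#' Binarizes the matrix at a uniform grid of `count` thresholds from the
#' minimum off-diagonal entry to `t_max` (both inclusive) and records, per
#' threshold, the average degree, clustering coefficient and node/link
#' counts.  When `null_reps > 0`, each threshold's clustering is compared
#' against an Erdős–Rényi Monte-Carlo null matched on nodes and links (see
#' [er_null()]), giving the null mean/SD and an exceedance p-value.
#'
#' @param m A `connectivity_matrix` (z-scale grand mean) or plain symmetric
#'   matrix with at least one finite off-diagonal entry.
#' @param t_max Upper end of the grid (default 0.6).
#' @param t_min Lower end of the grid; defaults to the minimum off-diagonal
#'   entry.  Supply a common value to compare conditions on one grid.
#' @param count Number of thresholds (default 6000).
#' @param null_reps Erdős–Rényi replicates per threshold (0 = no null).
#' @param null_mode,alpha,seed Passed to [er_null()] / [null_pvalue()];
#'   `alpha` is the significance level for the `significant` flag.
#' @param two_sided Use a two-sided null comparison (default one-sided
#'   exceedance).
#' @return Object of class `threshold_curve`: a data frame with columns
#'   `threshold`, `k_mean`, `clustering`, `n_nodes`, `n_links`, and when a
#'   null is requested `null_c_mean`, `null_c_sd`, `p`, `significant`.
#' @export
threshold_sweep <- function(m, t_max = 0.6, count = 6000, null_reps = 0,
                            null_mode = "matched", alpha = 0.01,
                            two_sided = FALSE, seed = 1, t_min = NULL) {
  a <- unclass(m)
  off <- a[upper.tri(a)]
  off <- off[is.finite(off)]
  if (!length(off)) stop("matrix has no finite off-diagonal entries")
  if (is.null(t_min)) t_min <- min(off)
  if (t_max < t_min)
    stop("'t_max' (", t_max, ") is below the minimum off-diagonal entry (",
         signif(t_min, 4), ")")
  grid <- seq(t_min, t_max, length.out = count)
  if (null_reps > 0) set.seed(as.integer(seed))

  k_mean <- clustering <- n_nodes <- n_links <- numeric(count)
  null_c_mean <- null_c_sd <- pval <- rep(NA_real_, count)
  for (i in seq_len(count)) {
    g <- binarize(m, grid[i])
    deg <- rowSums(g$adjacency)
    n_nodes[i] <- sum(deg > 0)
    n_links[i] <- sum(deg) / 2
    k_mean[i] <- if (n_nodes[i]) mean(deg[deg > 0]) else 0
    clustering[i] <- clustering_coefficient(g)
    if (null_reps > 0 && n_nodes[i] >= 2 && n_links[i] >= 1) {
      null <- er_null(n_nodes[i], n_links[i], replicates = null_reps,
                      mode = null_mode, seed = NULL)
      null_c_mean[i] <- mean(null$clustering)
      null_c_sd[i] <- stats::sd(null$clustering)
      pval[i] <- null_pvalue(clustering[i], null, two_sided = two_sided)
    }
  }
  out <- data.frame(threshold = grid, k_mean = k_mean, clustering = clustering,
                    n_nodes = n_nodes, n_links = n_links)
  if (null_reps > 0) {
    out$null_c_mean <- null_c_mean
    out$null_c_sd <- null_c_sd
    out$p <- pval
    out$significant <- !is.na(pval) & pval < alpha
  }
  attr(out, "condition") <- attr(m, "condition")
  attr(out, "t_range") <- c(t_min, t_max)
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Erdős–Rényi Monte-Carlo null distribution of the clustering coefficient
#'
#' In the default `"matched"` mode each replicate is a uniform random graph
#' with exactly `n_nodes` nodes and `n_links` links (the G(n, m) ensemble),
#' matching the observed graph's size; in `"probability"` mode edges are
#' independent Bernoulli(`p`) draws (the G(n, p) ensemble, for which the
#' expected clustering coefficient equals `p`).
#'
#' @param n_nodes Number of nodes.
#' @param n_links Number of links (matched mode); must not exceed
#'   `n_nodes (n_nodes - 1) / 2`.
#' @param replicates Number of Monte-Carlo replicates (default 1000).
#' @param mode `"matched"` or `"probability"`.
#' @param p Edge probability for `"probability"` mode (default 0.5).
#' @param seed Integer seed, or `NULL` to continue the current random
#'   stream (as the per-threshold sweep does).
#' @return Object of class `er_null`: list with `clustering` (replicate
#'   values), `n_nodes`, `n_links`, `mode`, `p`.
#' @export
er_null <- function(n_nodes, n_links = NULL, replicates = 1000,
                    mode = c("matched", "probability"), p = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (replicates <= 0) stop("'replicates' must be positive")
  max_links <- n_nodes * (n_nodes - 1) / 2
  if (mode == "matched") {
    if (is.null(n_links)) stop("'n_links' is required in matched mode")
    if (n_links > max_links)
      stop("n_links = ", n_links, " exceeds the maximum ", max_links,
           " for ", n_nodes, " nodes")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  cvals <- numeric(replicates)
  edges <- integer(replicates)
  for (r in seq_len(replicates)) {
    g <- if (mode == "matched")
      igraph::sample_gnm(n_nodes, n_links)
    else
      igraph::sample_gnp(n_nodes, p)
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    cvals[r] <- clustering_coefficient(a)
    edges[r] <- sum(a) / 2L
  }
  structure(list(clustering = cvals, n_edges = edges, n_nodes = n_nodes,
                 n_links = n_links, mode = mode,
                 p = if (mode == "probability") p else NA_real_),
            class = "er_null")
}

#' Monte-Carlo p-value against an Erdős–Rényi null
#'
#' Add-one exceedance p-value
#' `p = (1 + #\{null C >= observed\}) / (replicates + 1)`, never zero;
#' ties count as exceedances.  With `two_sided = TRUE` the smaller tail is
#' doubled (capped at 1).
#'
#' @param observed Observed clustering coefficient.
#' @param null An [er_null()] object.
#' @param two_sided Logical.
#' @return The p-value, in (0, 1\].
#' @export
null_pvalue <- function(observed, null, two_sided = FALSE) {
  cv <- null$clustering
  if (!length(cv)) stop("empty null distribution")
  r <- length(cv)
  p_up <- (1 + sum(cv >= observed)) / (r + 1)
  if (!two_sided) return(p_up)
  p_dn <- (1 + sum(cv <= observed)) / (r + 1)
  min(1, 2 * min(p_up, p_dn))
}

#' Export the binary adjacency matrix at a fixed threshold
#'
#' Binarizes the grand-mean matrix at `threshold` (default 0.35), reorders
#' regions as requested (e.g. by localization and lateralization) and
#' returns the 0/1 matrix with its average degree and clustering
#' coefficient.
#'
#' @param m A `connectivity_matrix` or plain symmetric matrix.
#' @param threshold Binarization threshold (default 0.35).
#' @param roi_order Optional permutation of the region labels.
#' @return List with `adjacency` (0/1 matrix in the requested order),
#'   `k_mean`, `clustering`, `threshold`.
#' @export
adjacency_export <- function(m, threshold = 0.35, roi_order = NULL) {
  g <- binarize(m, threshold)
  a <- g$adjacency
  if (!is.null(roi_order)) {
    if (!setequal(roi_order, rownames(a)) || length(roi_order) != nrow(a))
      stop("'roi_order' must be a permutation of the region labels")
    a <- a[roi_order, roi_order]
  }
  list(adjacency = a, k_mean = average_degree(g),
       clustering = clustering_coefficient(g), threshold = threshold)
}

#' Write a threshold curve as TSV
#'
#' @param curve A `threshold_curve`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_threshold_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.threshold_curve <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("Threshold curve%s: %d thresholds in [%.3f, %.3f]; <k> %.2f..%.2f\n",
              if (!is.null(cond) && !is.na(cond)) paste0(" [", cond, "]") else "",
              nrow(x), min(x$threshold), max(x$threshold),
              min(x$k_mean), max(x$k_mean)))
  if ("significant" %in% names(x))
    cat(sprintf("  %d/%d thresholds significant vs ER null\n",
                sum(x$significant, na.rm = TRUE), nrow(x)))
  invisible(x)
}

#' Plot a threshold curve
#'
#' Draws average degree and clustering coefficient against threshold (two
#' stacked base-graphics panels); the null clustering mean is overlaid as a
#' dashed line when present.
#'
#' @param x A `threshold_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.threshold_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$threshold, x$k_mean, type = "l", xlab = "threshold",
                 ylab = expression(group("<", k, ">")), ...)
  graphics::plot(x$threshold, x$clustering, type = "l", xlab = "threshold",
                 ylab = "C", ylim = c(0, 1), ...)
  if ("null_c_mean" %in% names(x))
    graphics::lines(x$threshold, x$null_c_mean, lty = 2L)
  invisible(x)
}
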