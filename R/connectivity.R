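#' Connectivity matrices
#'
#' A connectivity matrix is a symmetric regions x regions matrix of
#' association values with an `NA` diagonal (self-association is excluded
#' from all downstream graph computations), a scale flag (`"r"` for Pearson
#' correlations, `"z"` after the Fisher arc-hyperbolic-tangent transform), a
#' condition label and a subject identifier (`"grand_mean"` for group
#' averages).
#'
#' @param m Symmetric numeric matrix with identical row/column labels.
#' @param scale `"r"` or `"z"`.
#' @param condition Condition label.
#' @param subject_id Subject identifier or `"grand_mean"`.
#' @param n_subjects Number of subjects averaged (1 for single-subject).
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(m, scale = c("r", "z"), condition = NA_character_,
                                subject_id = NA_character_, n_subjects = 1L) {
  scale <- match.arg(scale)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) stop("matrix must be symmetric")
  m[lower.tri(m)] <- t(m)[lower.tri(m)]   # make symmetry exact
  diag(m) <- NA_real_
  off <- m[upper.tri(m)]
  if (scale == "r" && any(abs(off) > 1 + 1e-12, na.rm = TRUE))
    stop("r-scale entries must lie in [-1, 1]")
  structure(m, class = c("connectivity_matrix", class(m)),
            scale = scale, condition = condition, subject_id = subject_id,
            n_subjects = as.integer(n_subjects))
}

#' Pearson correlation matrix of a condition's beta series
#'
#' Correlates every pair of regions' single-trial beta series over the
#' trials of one condition.  Regions whose beta series have zero variance
#' get `NA` rows/columns (with a warning) and are excluded pairwise
#' downstream.
#'
#' @param x A `beta_series` object, or a trials x regions matrix.
#' @param condition Condition label selecting trials (required for a
#'   `beta_series`; ignored for a plain matrix except as metadata).
#' @return A `connectivity_matrix` on the r scale.
#' @export
pearson_matrix <- function(x, condition = NA_character_) {
  if (inherits(x, "beta_series")) {
    if (is.na(condition)) stop("'condition' is required for a beta_series")
    series <- condition_betas(x, condition)
    sid <- if (is.null(x$subject_id)) NA_character_ else x$subject_id
  } else {
    series <- as.matrix(x)
    sid <- NA_character_
  }
  if (nrow(series) < 3L)
    stop("need at least 3 trials per condition to correlate")
  sds <- apply(series, 2L, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance region(s) set to NA: ",
            paste(utils::head(colnames(series)[degenerate], 5L), collapse = ", "))
  cc <- suppressWarnings(stats::cor(series))
  cc[degenerate, ] <- NA_real_
  cc[, degenerate] <- NA_real_
  connectivity_matrix(cc, scale = "r", condition = condition, subject_id = sid)
}

#' Fisher z (arc-hyperbolic tangent) transform
#'
#' `z = arctanh(c)` applied elementwise after clipping `|c|` at
#' `1 - clip_eps`, so perfect correlations stay finite.
#'
#' @param m A `connectivity_matrix` on the r scale.
#' @param clip_eps Clipping distance from 1 (default `1e-7`).
#' @return A `connectivity_matrix` on the z scale.
#' @export
fisher_z <- function(m, clip_eps = 1e-7) {
  if (!identical(attr(m, "scale"), "r")) stop("input must be on the r scale")
  z <- atanh(pmax(pmin(unclass(m), 1 - clip_eps), -1 + clip_eps))
  connectivity_matrix(z, scale = "z", condition = attr(m, "condition"),
                      subject_id = attr(m, "subject_id"),
                      n_subjects = attr(m, "n_subjects"))
}

#' Grand-mean connectivity matrix over subjects
#'
#' Elementwise mean of the subjects' Fisher-z matrices for one condition;
#' missing entries are excluded pairwise, with per-entry counts kept in the
#' `n_used` attribute.
#'
#' @param z_matrices List of z-scale `connectivity_matrix` objects with
#'   identical region sets.
#' @return A z-scale `connectivity_matrix` with `subject_id = "grand_mean"`.
#' @export
grand_mean_matrix <- function(z_matrices) {
  if (!length(z_matrices)) stop("empty list of matrices")
  if (!all(vapply(z_matrices, function(m) identical(attr(m, "scale"), "z"), logical(1L))))
    stop("all matrices must be on the z scale")
  labs <- rownames(z_matrices[[1L]])
  if (!all(vapply(z_matrices, function(m) identical(rownames(m), labs), logical(1L))))
    stop("all matrices must share the same region set and order")
  arr <- simplify2array(lapply(z_matrices, unclass))
  gm <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
  gm[is.nan(gm)] <- NA_real_
  n_used <- apply(!is.na(arr), c(1L, 2L), sum)
  cond <- attr(z_matrices[[1L]], "condition")
  out <- connectivity_matrix(gm, scale = "z", condition = cond,
                             subject_id = "grand_mean",
                             n_subjects = length(z_matrices))
  attr(out, "n_used") <- n_used
  out
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("Connectivity matrix (%s scale): %d x %d, condition %s, %s; off-diag range [%.3f, %.3f]\n",
              attr(x, "scale"), nrow(x), ncol(x), attr(x, "condition"),
              if (identical(attr(x, "subject_id"), "grand_mean"))
                sprintf("grand mean of %d subjects", attr(x, "n_subjects"))
              else paste0("subject ", attr(x, "subject_id")),
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a connectivity matrix as labeled TSV with a JSON sidecar
#'
#' The matrix is written tab-delimited with region labels as header row and
#' first column, missing entries as `NA`; scale, condition and subject
#' count go to `<path>.json`.
#'
#' @param m A `connectivity_matrix`.
#' @param path Destination TSV path.
#' @return `read_connectivity_matrix` returns the `connectivity_matrix`;
#'   the writer returns `path` invisibly.
#' @export
write_connectivity_matrix <- function(m, path) {
  df <- data.frame(roi = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scale = attr(m, "scale"), condition = attr(m, "condition"),
               subject_id = attr(m, "subject_id"),
               n_subjects = attr(m, "n_subjects"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @export
read_connectivity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  diag(m) <- NA_real_
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(scale = "z", condition = NA, subject_id = NA, n_subjects = 1L)
  connectivity_matrix(m, scale = meta$scale,
                      condition = if (is.null(meta$condition)) NA_character_ else meta$condition,
                      subject_id = if (is.null(meta$subject_id)) NA_character_ else meta$subject_id,
                      n_subjects = if (is.null(meta$n_subjects)) 1L else meta$n_subjects)
}
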