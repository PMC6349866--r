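#' Behavioral retention tables
#'
#' Long-format table of correct-response counts: one row per subject per
#' condition, with columns `subject_id`, `group` (evaluation time, e.g.
#' `day5` / `day15`), `condition`, `correct_training`, `correct_testing`
#' and the derived `retention = correct_testing - correct_training`.
#'
#' @param df Data frame with the columns above (retention is recomputed).
#' @param n_items Items per condition (bounds check; default 12).
#' @return `df` with a `retention` column, classed `retention_table`.
#' @export
retention_table <- function(df, n_items = 12) {
  required <- c("subject_id", "group", "condition", "correct_training", "correct_testing")
  if (!all(required %in% names(df)))
    stop("retention table needs columns: ", paste(required, collapse = ", "))
  df <- as.data.frame(df)[, required]
  counts <- c(df$correct_training, df$correct_testing)
  if (length(counts) && (any(counts < 0) || any(counts > n_items)))
    stop("counts must lie in [0, ", n_items, "]")
  df$retention <- retention(df$correct_testing, df$correct_training)
  class(df) <- c("retention_table", "data.frame")
  df
}

#' Retention score
#'
#' Correct responses at testing minus correct responses at training; may be
#' negative (forgetting).
#'
#' @param correct_testing,correct_training Non-negative counts.
#' @return Integer difference(s).
#' @export
retention <- function(correct_testing, correct_training) {
  if (any(correct_testing < 0) || any(correct_training < 0))
    stop("counts must be non-negative")
  as.integer(correct_testing) - as.integer(correct_training)
}

#' Read / write retention tables as CSV
#'
#' @param tab A [retention_table()].
#' @param path File path.
#' @return The reader returns a [retention_table()].
#' @export
write_retention_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[, c("subject_id", "group", "condition",
                                          "correct_training", "correct_testing")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_retention_table
#' @export
read_retention_table <- function(path, n_items = 12) {
  retention_table(utils::read.csv(path, stringsAsFactors = FALSE), n_items = n_items)
}

#' Greenhouse–Geisser epsilon
#'
#' Sphericity correction factor computed from the k x k covariance matrix
#' of the within-subject condition scores, using the classical
#' element-means formula on the double-centered covariance; bounded in
#' `[1/(k-1), 1]`.  Corrected degrees of freedom are `epsilon` times the
#' uncorrected ones.
#'
#' @param S k x k covariance matrix of the repeated measures (k >= 2).
#' @return Epsilon, a single number.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2L || ncol(S) != k) stop("'S' must be a k x k covariance matrix, k >= 2")
  s_bar <- mean(S)
  s_diag <- mean(diag(S))
  row_means <- rowMeans(S)
  num <- (k * (s_diag - s_bar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * s_bar^2)
  eps <- num / den
  min(1, max(1 / (k - 1), eps))
}

#' Mixed repeated-measures ANOVA on retention
#'
#' The behavioral model: reminder condition as the within-subjects factor,
#' evaluation time (group) as the between-subjects factor.  Sums of squares
#' follow the standard balanced mixed-design decomposition (fitted with
#' [stats::aov()] and an `Error(subject/condition)` stratum structure).
#' Sphericity of the within factor is tested with Mauchly's test; when it
#' rejects at `sphericity_alpha`, Greenhouse–Geisser-corrected degrees of
#' freedom and p-values are used for the within and interaction effects
#' (both corrected and uncorrected values are always reported).  Bonferroni
#' post-hoc paired comparisons of the conditions are attached.
#'
#' @param tab A [retention_table()] with >= 2 subjects per group and every
#'   condition observed for every subject.
#' @param value Column to analyze (default `"retention"`).
#' @param sphericity_alpha Alpha for Mauchly's gate (default 0.05).
#' @return Object of class `rm_anova`: list with `effects` (data frame:
#'   effect, F, df_num, df_den, p, eta_p2, and GG-corrected columns for
#'   within effects), `epsilon`, `mauchly_p`, `corrected`, `posthoc`.
#' @export
mixed_rm_anova <- function(tab, value = "retention", sphericity_alpha = 0.05) {
  df <- as.data.frame(tab)
  df$y <- df[[value]]
  df$subject_id <- factor(df$subject_id)
  df$condition <- factor(df$condition)
  df$group <- factor(df$group)
  k <- nlevels(df$condition)
  cells <- table(df$subject_id, df$condition)
  if (any(cells != 1L))
    stop("every subject needs exactly one observation per condition")
  if (any(table(unique(df[c("subject_id", "group")])$group) < 2L))
    stop("need at least 2 subjects per group")

  fit <- stats::aov(y ~ group * condition + Error(subject_id / condition), data = df)
  s_between <- summary(fit)[["Error: subject_id"]][[1L]]
  s_within <- summary(fit)[["Error: subject_id:condition"]][[1L]]
  get_row <- function(s, name) {
    i <- match(name, trimws(rownames(s)))
    er <- nrow(s)      # Residuals row
    ss_eff <- s[i, "Sum Sq"]; ss_err <- s[er, "Sum Sq"]
    f <- s[i, "F value"]; p <- s[i, "Pr(>F)"]
    if (ss_eff < 1e-9 && (!is.finite(f) || ss_err < 1e-9)) { f <- 0; p <- 1 }  # constant data
    data.frame(effect = name, F = f,
               df_num = s[i, "Df"], df_den = s[er, "Df"], p = p,
               eta_p2 = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
               stringsAsFactors = FALSE)
  }
  effects <- rbind(get_row(s_between, "group"),
                   get_row(s_within, "condition"),
                   get_row(s_within, "group:condition"))

  # pooled within-group covariance of the condition scores
  ymat <- tapply(df$y, list(df$subject_id, df$condition), mean)
  subj_group <- factor(df$group[match(rownames(ymat), df$subject_id)])
  centered <- ymat - rowsum(ymat, subj_group)[as.integer(subj_group), , drop = FALSE] /
    as.vector(table(subj_group)[as.integer(subj_group)])
  S <- crossprod(centered) / (nrow(ymat) - nlevels(df$group))
  eps <- gg_epsilon(S)
  mlm <- stats::lm(ymat ~ subj_group)
  mauchly_p <- tryCatch(stats::mauchly.test(mlm, X = ~1)$p.value,
                        error = function(e) NA_real_)
  corrected <- is.finite(mauchly_p) && mauchly_p < sphericity_alpha

  within_idx <- effects$effect %in% c("condition", "group:condition")
  effects$df_num_gg <- ifelse(within_idx, effects$df_num * eps, NA_real_)
  effects$df_den_gg <- ifelse(within_idx, effects$df_den * eps, NA_real_)
  effects$p_gg <- ifelse(within_idx,
                         stats::pf(effects$F, effects$df_num * eps,
                                   effects$df_den * eps, lower.tail = FALSE),
                         NA_real_)
  effects$p_reported <- ifelse(within_idx & corrected, effects$p_gg, effects$p)

  posthoc <- lapply(split(df, df$group), function(d)
    bonferroni_posthoc(d, value = "y"))

  structure(list(effects = effects, epsilon = eps, mauchly_p = mauchly_p,
                 corrected = corrected, posthoc = posthoc,
                 error_structure = "mixed (within: condition, between: group)"),
            class = "rm_anova")
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Paired t-tests for every pair of conditions, with p-values multiplied by
#' the number of comparisons and capped at 1.  Pairs with identical scores
#' (zero difference throughout) get `p_adj = 1`.
#'
#' @param df Long data frame with `subject_id`, `condition` and the score
#'   column `value`.
#' @param value Name of the score column.
#' @return Data frame: `pair`, `t`, `df`, `p`, `p_adj`, `mean_diff`.
#' @export
bonferroni_posthoc <- function(df, value = "retention") {
  df$condition <- factor(df$condition)
  conds <- levels(df$condition)
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    wide <- merge(df[df$condition == pr[1L], c("subject_id", value)],
                  df[df$condition == pr[2L], c("subject_id", value)],
                  by = "subject_id")
    d <- wide[[2L]] - wide[[3L]]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = if (mean(d) == 0) 0 else Inf,
                 parameter = length(d) - 1L, p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- stats::t.test(wide[[2L]], wide[[3L]], paired = TRUE)
    data.frame(pair = paste(pr, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, m * tt$p.value),
               mean_diff = mean(d), stringsAsFactors = FALSE)
  }))
  out
}

#' One-way within-subject ANOVA of pooled region beta-values
#'
#' Runs, per pooled region, a one-way ANOVA with reminder condition as the
#' factor.  The default error structure is within-subject (repeated
#' measures, `Error(subject)` stratum); `error = "between"` treats
#' observations as independent (one-way between-subjects ANOVA), the
#' structure implied by some reported degrees of freedom.  Bonferroni
#' paired post-hocs are attached per region.
#'
#' @param df Long data frame: `subject_id`, `region`, `condition`, `beta`.
#' @param error `"within"` (default) or `"between"`.
#' @param alpha Significance level for the `significant` flag.
#' @return Object of class `roi_anova`: list of per-region `effects` rows
#'   (data frame) plus `posthoc` per region and the error structure label.
#' @export
roi_rm_anova <- function(df, error = c("within", "between"), alpha = 0.05) {
  error <- match.arg(error)
  df <- as.data.frame(df)
  df$subject_id <- factor(df$subject_id)
  df$condition <- factor(df$condition)
  if (error == "within" && nlevels(df$subject_id) < 2L)
    stop("within-subject ANOVA needs at least 2 subjects")
  regions <- unique(df$region)
  rows <- list(); posthoc <- list()
  for (rg in regions) {
    d <- df[df$region == rg, , drop = FALSE]
    if (error == "within") {
      if (any(table(d$subject_id, d$condition) != 1L))
        stop("region ", rg, ": every subject needs one value per condition")
      fit <- stats::aov(beta ~ condition + Error(subject_id), data = d)
      s <- summary(fit)[["Error: Within"]][[1L]]
    } else {
      fit <- stats::aov(beta ~ condition, data = d)
      s <- summary(fit)[[1L]]
    }
    i <- match("condition", trimws(rownames(s)))
    er <- nrow(s)
    ss_eff <- s[i, "Sum Sq"]; ss_err <- s[er, "Sum Sq"]
    f <- s[i, "F value"]; p <- s[i, "Pr(>F)"]
    if (ss_eff < 1e-9 && (!is.finite(f) || ss_err < 1e-9)) { f <- 0; p <- 1 }
    rows[[rg]] <- data.frame(region = rg, F = f,
                             df_num = s[i, "Df"], df_den = s[er, "Df"], p = p,
                             eta_p2 = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
                             significant = p < alpha,
                             stringsAsFactors = FALSE)
    posthoc[[rg]] <- bonferroni_posthoc(d, value = "beta")
  }
  structure(list(effects = do.call(rbind, c(rows, make.row.names = FALSE)),
                 posthoc = posthoc, error_structure = error, alpha = alpha),
            class = "roi_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (", x$error_structure, ")\n", sep = "")
  print(x$effects[, c("effect", "F", "df_num", "df_den", "p_reported", "eta_p2")],
        digits = 4L, row.names = FALSE)
  cat(sprintf("Mauchly p = %.4g; GG epsilon = %.4f; correction %s\n",
              x$mauchly_p, x$epsilon,
              if (x$corrected) "applied" else "not applied"))
  invisible(x)
}

#' @export
print.roi_anova <- function(x, ...) {
  cat("Per-region one-way ANOVA (", x$error_structure, "-subject error)\n", sep = "")
  print(x$effects, digits = 4L, row.names = FALSE)
  invisible(x)
}
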