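#' Read / write region-level signal tables
#'
#' Signals are stored as TSV with one row per scan and one labeled column
#' per region.
#'
#' @param signal Scans x regions matrix (or a `bold_sim`).
#' @param path File path.
#' @return The reader returns a scans x regions matrix.
#' @export
write_signal_table <- function(signal, path) {
  if (inherits(signal, "bold_sim")) signal <- signal$signal
  utils::write.table(as.data.frame(signal), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
}

#' Read / write beta series as TSV
#'
#' One row per trial (columns `trial`, `condition`, then one column per
#' region); the non-trial coefficients (pause baseline, microphone and
#' filler regressors, intercept) are appended as extra rows with condition
#' `"_other_"` so that region beta-value contrasts survive the round trip.
#'
#' @param bs A `beta_series`.
#' @param path File path.
#' @return The reader returns a `beta_series`.
#' @export
write_beta_series <- function(bs, path) {
  stopifnot(inherits(bs, "beta_series"))
  top <- data.frame(trial = rownames(bs$betas), condition = bs$condition,
                    bs$betas, check.names = FALSE, row.names = NULL)
  if (!is.null(bs$other) && nrow(bs$other)) {
    bottom <- data.frame(trial = rownames(bs$other), condition = "_other_",
                         bs$other, check.names = FALSE, row.names = NULL)
    top <- rbind(top, bottom)
  }
  utils::write.table(top, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_series
#' @export
read_beta_series <- function(path, subject_id = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  is_other <- df$condition == "_other_"
  betas <- as.matrix(df[!is_other, -(1:2), drop = FALSE])
  rownames(betas) <- df$trial[!is_other]
  other <- as.matrix(df[is_other, -(1:2), drop = FALSE])
  rownames(other) <- df$trial[is_other]
  ids <- suppressWarnings(as.integer(sub("^trial_([0-9]+).*$", "\\1",
                                         rownames(betas))))
  structure(list(betas = betas, condition = df$condition[!is_other],
                 item_id = ids, other = other, subject_id = subject_id),
            class = "beta_series")
}
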