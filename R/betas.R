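#' Fit single-trial betas by ordinary least squares
#'
#' Estimates one amplitude per picture trial per region.  The default LS-A
#' mode solves one GLM containing every trial regressor simultaneously; the
#' LS-S mode refits one GLM per trial in which the remaining trials are
#' pooled per condition, keeping only the target trial's coefficient.
#'
#' @param signal Scans x regions numeric matrix (labeled columns), or a
#'   `bold_sim` object from [simulate_bold()].
#' @param design A [build_trial_design()] object with trialwise columns.
#' @param mode `"lsa"` (all trials in one model, default) or `"lss"`.
#' @param subject_id Optional subject identifier stored in the result.
#' @return Object of class `beta_series`: list with `betas` (trials x
#'   regions matrix, rows in run order), `condition` (per-trial labels),
#'   `item_id`, `other` (remaining coefficients x regions, incl. the pause
#'   baseline when modeled), `subject_id`.
#' @export
fit_trial_betas <- function(signal, design, mode = c("lsa", "lss"),
                            subject_id = NULL) {
  mode <- match.arg(mode)
  if (inherits(signal, "bold_sim")) {
    if (is.null(subject_id)) subject_id <- "sim"
    signal <- signal$signal
  }
  signal <- as.matrix(signal)
  X <- design$X
  if (nrow(signal) != nrow(X))
    stop("signal has ", nrow(signal), " scans but design has ", nrow(X))
  info <- design$trial_info
  if (!nrow(info)) stop("design has no trialwise columns; rebuild with trialwise = TRUE")

  if (mode == "lsa") {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      stop("design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    coefs <- qr.coef(qx, signal)
    trial_betas <- coefs[info$column, , drop = FALSE]
    other <- coefs[setdiff(rownames(coefs), info$column), , drop = FALSE]
  } else {
    fixed <- setdiff(colnames(X), info$column)
    trial_betas <- matrix(NA_real_, nrow(info), ncol(signal),
                          dimnames = list(info$column, colnames(signal)))
    for (i in seq_len(nrow(info))) {
      others <- info[-i, , drop = FALSE]
      pooled <- vapply(split(others$column, others$condition),
                       function(cc) rowSums(X[, cc, drop = FALSE]),
                       numeric(nrow(X)))
      Xi <- cbind(X[, info$column[i], drop = FALSE], pooled,
                  X[, fixed, drop = FALSE])
      qx <- qr(Xi)
      if (qx$rank < ncol(Xi)) stop("rank-deficient LS-S design at trial ", i)
      trial_betas[i, ] <- qr.coef(qx, signal)[1L, ]
    }
    qx <- qr(X)
    other <- qr.coef(qx, signal)[fixed, , drop = FALSE]
  }

  structure(list(betas = trial_betas, condition = info$condition,
                 item_id = info$item_id, other = other,
                 subject_id = subject_id),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("Beta series%s: %d trials x %d regions; conditions: %s\n",
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              nrow(x$betas), ncol(x$betas),
              paste(sprintf("%s(%d)", names(table(x$condition)), table(x$condition)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract the per-condition beta series
#'
#' @param x A `beta_series` object.
#' @param condition Condition label.
#' @return Trials x regions matrix for that condition, in run order.
#' @export
condition_betas <- function(x, condition) {
  stopifnot(inherits(x, "beta_series"))
  x$betas[x$condition == condition, , drop = FALSE]
}

#' Zero-phase band-pass filter along the trial axis
#'
#' Applies a Butterworth band-pass (default 0.01 to 0.25 Hz) forwards and
#' backwards (zero phase) along the trial axis of a beta series, treating
#' the trial index as a uniformly sampled axis.  When the requested upper
#' edge reaches or exceeds the Nyquist frequency of that axis — as it does
#' for typical beta-series sampling intervals of 12 s and more — the filter
#' degrades to the high-pass part alone, with a warning.  The series is
#' reflection-padded before filtering to suppress end transients.
#'
#' @param series Numeric vector, or trials x regions matrix (filtered per
#'   column).
#' @param low_hz,high_hz Pass-band edges, Hz.
#' @param sampling_rate Sampling rate of the trial axis, Hz (e.g.
#'   `1 / (mean ITI + trial duration)`).
#' @param order Butterworth order (default 4).
#' @return Filtered series, same shape as the input.
#' @export
bandpass_beta_series <- function(series, low_hz = 0.01, high_hz = 0.25,
                                 sampling_rate, order = 4) {
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz")
  nyq <- sampling_rate / 2
  if (low_hz >= nyq) stop("'low_hz' must be below the Nyquist frequency ", nyq)
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1L) else as.matrix(series)
  n <- nrow(x)
  min_len <- 2L * (2L * order + 1L)
  if (n < min_len)
    stop("series of length ", n, " is too short for a zero-phase order-",
         order, " filter (needs >= ", min_len,
         "); pad the series or skip filtering")
  if (high_hz >= nyq) {
    warning("upper band edge ", high_hz, " Hz is at/above Nyquist (", nyq,
            " Hz); applying the high-pass part only")
    flt <- signal::butter(order, low_hz / nyq, type = "high")
  } else {
    flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  out <- apply(x, 2L, function(col) filtfilt_padded(flt, col))
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  if (vec) drop(out) else out
}

# zero-phase filtering with odd reflection padding at both ends; the mean is
# removed first (it is not passed by the band anyway) so the slow high-pass
# transient does not leak in from the padding
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  mu <- mean(x)
  x <- x - mu
  pad <- n - 1L
  head_pad <- 2 * x[1L] - rev(x[2L:(pad + 1L)])
  tail_pad <- 2 * x[n] - rev(x[(n - pad):(n - 1L)])
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Region beta-values against the inter-trial baseline
#'
#' For every region and condition, the beta-value is the mean single-trial
#' beta of that condition minus the baseline beta (the pooled inter-trial
#' pause regressor).  Regions are additionally pooled into the seven large
#' bilateral regions by unweighted averaging of member-region values.
#'
#' @param x A `beta_series` fitted from a design with `include_pause = TRUE`,
#'   or a trials x regions matrix (then `baseline` must be given).
#' @param baseline Optional named numeric vector of baseline betas per
#'   region; defaults to the `"pause"` row of `x$other`.
#' @param pooling Data frame with columns `roi`, `region` mapping atlas
#'   labels to pooled regions (default [region_pooling_map()]); every `roi`
#'   must exist in the beta series.
#' @return List with `roi` (data frame region x condition of beta-values)
#'   and `pooled` (data frame pooled-region x condition).
#' @export
roi_beta_values <- function(x, baseline = NULL, pooling = region_pooling_map()) {
  if (inherits(x, "beta_series")) {
    betas <- x$betas; cond <- x$condition
    if (is.null(baseline)) {
      if (!"pause" %in% rownames(x$other))
        stop("no pause regressor in the fit; supply 'baseline' explicitly")
      baseline <- x$other["pause", ]
    }
  } else stop("'x' must be a beta_series")
  conds <- unique(cond)
  bv <- vapply(conds, function(cc)
    colMeans(betas[cond == cc, , drop = FALSE]) - baseline,
    numeric(ncol(betas)))
  roi_df <- data.frame(roi = colnames(betas), bv, check.names = FALSE,
                       stringsAsFactors = FALSE, row.names = NULL)
  pooled_df <- NULL
  if (!is.null(pooling)) {
    missing_roi <- setdiff(pooling$roi, roi_df$roi)
    if (length(missing_roi))
      stop("pooling map names unknown region(s): ",
           paste(missing_roi, collapse = ", "))
    pooled_df <- do.call(rbind, lapply(split(pooling$roi, pooling$region),
      function(members) {
        vals <- colMeans(roi_df[match(members, roi_df$roi), conds, drop = FALSE])
        as.data.frame(as.list(vals), check.names = FALSE)
      }))
    pooled_df <- data.frame(region = rownames(pooled_df), pooled_df,
                            check.names = FALSE, row.names = NULL)
  }
  list(roi = roi_df, pooled = pooled_df)
}
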