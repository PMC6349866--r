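# Regressor construction: boxcar convolved with the canonical HRF on a fine
# grid (dt seconds), then sampled at scan acquisition times.

convolved_regressor <- function(onset, duration, n_scans, tr, hrf = hrf_params(),
                                dt = 0.01) {
  tf <- seq(0, hrf$kernel_length + duration, by = dt)
  h <- hrf_fun(tf, hrf) / hrf_peak_value(hrf)
  nb <- max(1L, round(duration / dt))
  conv <- stats::convolve(h, rep(1, nb), type = "open")[seq_along(tf)] * dt
  scan_t <- (seq_len(n_scans) - 1L) * tr
  stats::approx(tf, conv, xout = scan_t - onset, yleft = 0, yright = 0)$y
}

#' Build a single-trial GLM design matrix
#'
#' One regressor per learned-item picture trial (HRF-convolved 4 s boxcar,
#' sampled at scan times), pooled regressors for the microphone events of
#' each condition, the filler pictures, the filler microphones and — when
#' `include_pause` — the inter-trial pauses (mirroring the nine-regressor
#' condition-level structure when `trialwise = FALSE`), plus optional
#' nuisance columns and an intercept.
#'
#' @param events An [event_table()]; every event must end before
#'   `n_scans * tr`.
#' @param n_scans Number of acquired volumes.
#' @param tr Repetition time, seconds.
#' @param hrf An [hrf_params()] object.
#' @param nuisance Optional scans x p matrix of nuisance regressors (e.g.
#'   the six head-movement parameters).
#' @param trialwise If `TRUE` (default) each picture trial gets its own
#'   column (LS-A estimation); if `FALSE` picture regressors are pooled per
#'   condition.
#' @param include_pause Model the inter-trial pauses as a pooled regressor
#'   (used as the baseline for region beta-value contrasts).
#' @param intercept Append an intercept column.
#' @return Object of class `design_matrix`: list with `X` (scans x
#'   regressors, labeled), `trial_info` (data frame mapping trial columns to
#'   item and condition; empty when pooled), `tr`.
#' @export
build_trial_design <- function(events, n_scans, tr, hrf = hrf_params(),
                               nuisance = NULL, trialwise = TRUE,
                               include_pause = TRUE, intercept = TRUE) {
  if (nrow(events) && any(events$onset + events$duration > n_scans * tr + 1e-9))
    stop("event outside run: all events must end before n_scans * tr")
  cols <- list()
  trial_info <- data.frame(column = character(0), item_id = integer(0),
                           condition = character(0), stringsAsFactors = FALSE)

  pics <- events[events$event_kind == "picture", , drop = FALSE]
  if (nrow(pics)) {
    if (trialwise) {
      for (i in seq_len(nrow(pics))) {
        nm <- sprintf("trial_%03d_%s", pics$item_id[i], pics$condition[i])
        cols[[nm]] <- convolved_regressor(pics$onset[i], pics$duration[i],
                                          n_scans, tr, hrf)
        trial_info <- rbind(trial_info,
                            data.frame(column = nm, item_id = pics$item_id[i],
                                       condition = pics$condition[i],
                                       stringsAsFactors = FALSE))
      }
    } else {
      for (cc in unique(pics$condition)) {
        sel <- pics[pics$condition == cc, , drop = FALSE]
        reg <- rowSums(vapply(seq_len(nrow(sel)), function(i)
          convolved_regressor(sel$onset[i], sel$duration[i], n_scans, tr, hrf),
          numeric(n_scans)))
        cols[[paste0("pic_", cc)]] <- reg
      }
    }
  }

  pooled <- function(sel) {
    if (!nrow(sel)) return(NULL)
    rowSums(vapply(seq_len(nrow(sel)), function(i)
      convolved_regressor(sel$onset[i], sel$duration[i], n_scans, tr, hrf),
      numeric(n_scans)))
  }
  mics <- events[events$event_kind == "microphone", , drop = FALSE]
  for (cc in unique(mics$condition))
    cols[[paste0("mic_", cc)]] <- pooled(mics[mics$condition == cc, , drop = FALSE])
  fp <- pooled(events[events$event_kind == "filler_picture", , drop = FALSE])
  if (!is.null(fp)) cols[["filler_pic"]] <- fp
  fm <- pooled(events[events$event_kind == "filler_microphone", , drop = FALSE])
  if (!is.null(fm)) cols[["filler_mic"]] <- fm

  if (include_pause && nrow(events)) {
    ev <- events[order(events$onset), , drop = FALSE]
    offs <- ev$onset + ev$duration
    gap_on <- c(0, offs)
    gap_off <- c(ev$onset, n_scans * tr)
    keep <- gap_off - gap_on > 1e-9
    gaps <- data.frame(onset = gap_on[keep], duration = (gap_off - gap_on)[keep])
    cols[["pause"]] <- pooled(gaps)
  }

  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance matrix must have n_scans rows")
    if (is.null(colnames(nuisance))) colnames(nuisance) <- paste0("nuis_", seq_len(ncol(nuisance)))
    for (j in seq_len(ncol(nuisance))) cols[[colnames(nuisance)[j]]] <- nuisance[, j]
  }
  if (intercept) cols[["intercept"]] <- rep(1, n_scans)

  if (!length(cols)) stop("design would be empty: no events, nuisance or intercept")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyDuplicated(colnames(X))) stop("regressor labels must be unique")
  zero_trial <- trial_info$column[colSums(abs(X[, trial_info$column, drop = FALSE])) == 0]
  if (length(zero_trial))
    stop("all-zero trial column(s): ", paste(zero_trial, collapse = ", "))
  structure(list(X = X, trial_info = trial_info, tr = tr), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d scans x %d regressors (%d trialwise), TR %.2f s\n",
              nrow(x$X), ncol(x$X), nrow(x$trial_info), x$tr))
  invisible(x)
}
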