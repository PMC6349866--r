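#' Planted connectivity structure for the BOLD simulator
#'
#' Defines the community structure planted in the trial amplitudes: regions
#' are assigned to blocks, and for every condition a target trial-amplitude
#' correlation matrix is built with one correlation inside blocks and a
#' (lower) one between blocks.  Trial amplitude vectors are then drawn from
#' a multivariate normal with this correlation structure, so that
#' conditions with higher planted correlations yield denser beta-series
#' networks downstream.
#'
#' The default condition correlations emulate the study conditions the
#' package's synthetic cohorts represent: the incomplete-reminder condition
#' (`Rc`) is planted densest, and the complete-reminder (`Rw`) and
#' no-reminder (`Nr`) conditions are similar to each other and sparser.
#'
#' @param roi_labels Character vector of region labels (default the
#'   90-region parcellation of [aal90_labels()]).
#' @param n_blocks Number of equally sized communities (default 3).
#' @param within_block_corr Named numeric vector: within-block amplitude
#'   correlation per condition, each in \[-1, 1\].
#' @param between_block_corr Named numeric vector: between-block amplitude
#'   correlation per condition.
#' @param amp_sd Trial-amplitude standard deviation (signal units).
#' @return An object of class `planted_structure`: list with `blocks`
#'   (integer assignment per region), `roi_labels`, `sigma` (named list of
#'   condition covariance matrices) and `amp_sd`.
#' @export
planted_structure <- function(roi_labels = aal90_labels(), n_blocks = 3,
                              within_block_corr = c(Rc = 0.70, Rw = 0.50, Nr = 0.50),
                              between_block_corr = c(Rc = 0.38, Rw = 0.28, Nr = 0.26),
                              amp_sd = 1) {
  n <- length(roi_labels)
  if (anyDuplicated(roi_labels)) stop("region labels must be unique")
  conds <- names(within_block_corr)
  if (is.null(conds) || !identical(sort(conds), sort(names(between_block_corr))))
    stop("'within_block_corr' and 'between_block_corr' must be named by the same conditions")
  blocks <- rep(seq_len(n_blocks), length.out = n)
  blocks <- sort(blocks)
  same_block <- outer(blocks, blocks, "==")
  sigma <- lapply(conds, function(cc) {
    w <- within_block_corr[[cc]]; b <- between_block_corr[[cc]]
    R <- ifelse(same_block, w, b)
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("planted correlations for condition '", cc,
           "' do not give a positive semi-definite matrix")
    S <- R * amp_sd^2
    dimnames(S) <- list(roi_labels, roi_labels)
    S
  })
  names(sigma) <- conds
  structure(list(blocks = blocks, roi_labels = roi_labels,
                 sigma = sigma, amp_sd = amp_sd),
            class = "planted_structure")
}

#' Simulate region-level BOLD signals for one subject
#'
#' Forward model inverting the single-trial GLM: every picture trial draws a
#' region-amplitude vector from its condition's multivariate normal (mean
#' `amp_mean`, covariance from `planted`); each region's signal is the sum
#' over trials of amplitude times the HRF-convolved stimulus boxcar, plus
#' white Gaussian noise of standard deviation `noise_sd`.  Filler-trial
#' amplitudes are drawn independently per region; microphone events
#' contribute a fixed amplitude (`microphone_amp`) so their regressors are
#' identifiable.
#'
#' @param events An [event_table()].
#' @param planted A [planted_structure()] covering every condition in
#'   `events`.
#' @param tr Repetition time, seconds.
#' @param noise_sd Additive Gaussian noise SD, signal units.
#' @param amp_mean Mean trial amplitude.
#' @param microphone_amp Amplitude of microphone events (all regions).
#' @param hrf An [hrf_params()] object.
#' @param seed Integer seed.
#' @return Object of class `bold_sim`: list with `signal` (scans x regions
#'   matrix, labeled columns), `amplitudes` (picture-trial x region matrix),
#'   `trial_condition`, `events`, `tr`.
#' @export
simulate_bold <- function(events, planted, tr = 2.5, noise_sd = 1,
                          amp_mean = 1, microphone_amp = 0.5,
                          hrf = hrf_params(), seed = 1) {
  set.seed(as.integer(seed))
  labels <- planted$roi_labels
  n_roi <- length(labels)
  run_dur <- attr(events, "run_duration")
  if (is.null(run_dur)) run_dur <- if (nrow(events)) max(events$onset + events$duration) + 10 else 0
  n_scans <- ceiling(run_dur / tr)

  pics <- events[events$event_kind %in% picture_kinds, , drop = FALSE]
  n_trials <- nrow(pics)
  amps <- matrix(0, n_trials, n_roi, dimnames = list(NULL, labels))
  for (i in seq_len(n_trials)) {
    cc <- pics$condition[i]
    amps[i, ] <- if (cc %in% names(planted$sigma))
      MASS::mvrnorm(1L, mu = rep(amp_mean, n_roi), Sigma = planted$sigma[[cc]])
    else
      rep(amp_mean, n_roi)   # fillers: fixed amplitude (pooled regressor)
  }
  rownames(amps) <- sprintf("trial_%03d_%s", pics$item_id, pics$condition)

  signal <- matrix(0, n_scans, n_roi, dimnames = list(NULL, labels))
  if (n_trials && n_scans) {
    for (i in seq_len(n_trials)) {
      reg <- convolved_regressor(pics$onset[i], pics$duration[i], n_scans, tr, hrf)
      signal <- signal + tcrossprod(reg, amps[i, ])
    }
    mics <- events[events$event_kind %in% microphone_kinds, , drop = FALSE]
    for (i in seq_len(nrow(mics))) {
      reg <- convolved_regressor(mics$onset[i], mics$duration[i], n_scans, tr, hrf)
      signal <- signal + reg %o% rep(microphone_amp, n_roi)
    }
  }
  if (noise_sd > 0)
    signal <- signal + matrix(stats::rnorm(length(signal), 0, noise_sd), n_scans, n_roi)

  structure(list(signal = signal, amplitudes = amps,
                 trial_condition = pics$condition, events = events, tr = tr),
            class = "bold_sim")
}

#' Simulate behavioral correct-response tables
#'
#' Draws per-subject correct-response counts (0 to `n_items` per condition)
#' at training and at testing as clipped rounded Gaussians.  Training counts
#' share one mean across conditions (`learning_mean`); testing counts use
#' `condition_means`, so retention (testing minus training) inherits the
#' planted condition ordering.
#'
#' @param n_subjects Number of subjects.
#' @param condition_means Named numeric vector of testing-count means per
#'   condition, each in \[0, n_items\].
#' @param learning_mean Mean training count, shared by conditions.
#' @param sd Gaussian SD of both counts.
#' @param n_items Items per condition (default 12).
#' @param group Group label stored in the table (e.g. `"day5"`).
#' @param seed Integer seed.
#' @return A [retention_table()].
#' @export
simulate_behavior <- function(n_subjects, condition_means = c(Rc = 9.1, Rw = 8.8, Nr = 5.9),
                              learning_mean = 9.4, sd = 1.2, n_items = 12,
                              group = "day5", seed = 1) {
  if (any(condition_means < 0 | condition_means > n_items))
    stop("'condition_means' must lie in [0, n_items]")
  set.seed(as.integer(seed))
  conds <- names(condition_means)
  if (n_subjects == 0L)
    return(retention_table(data.frame(subject_id = character(0), group = character(0),
                                      condition = character(0),
                                      correct_training = integer(0),
                                      correct_testing = integer(0)), n_items = n_items))
  clip <- function(x) as.integer(pmin(n_items, pmax(0, round(x))))
  df <- expand.grid(condition = conds, subject_id = sprintf("%s_s%02d", group, seq_len(n_subjects)),
                    stringsAsFactors = FALSE)[, 2:1]
  df$group <- group
  df$correct_training <- clip(stats::rnorm(nrow(df), learning_mean, sd))
  df$correct_testing <- clip(stats::rnorm(nrow(df), condition_means[df$condition], sd))
  retention_table(df[, c("subject_id", "group", "condition",
                         "correct_training", "correct_testing")], n_items = n_items)
}

#' Simulate a full multi-subject cohort
#'
#' Generates, for each subject, one testing-session event design and the
#' corresponding region-level BOLD run with planted condition-dependent
#' connectivity.  Per-subject seeds are derived deterministically from
#' `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param planted A [planted_structure()].
#' @param n_items_per_condition,n_fillers,iti_mean,iti_sd Design parameters,
#'   see [simulate_testing_design()].
#' @param tr,noise_sd,amp_mean,hrf Signal parameters, see [simulate_bold()].
#' @param group Group label.
#' @param seed Integer base seed.
#' @return List of class `bold_cohort`: one `bold_sim` per subject, named
#'   by subject id; attribute `planted` keeps the generating structure.
#' @export
simulate_cohort <- function(n_subjects, planted = planted_structure(),
                            n_items_per_condition = 12, n_fillers = 12,
                            iti_mean = 8, iti_sd = 1, tr = 2.5, noise_sd = 1,
                            amp_mean = 1, hrf = hrf_params(),
                            group = "day5", seed = 1) {
  seed <- as.integer(seed)
  conds <- names(planted$sigma)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    ev <- simulate_testing_design(n_items_per_condition, n_fillers, iti_mean, iti_sd,
                                  conditions = conds, seed = seed + 1000L * s)
    simulate_bold(ev, planted, tr = tr, noise_sd = noise_sd, amp_mean = amp_mean,
                  hrf = hrf, seed = seed + 1000L * s + 1L)
  })
  names(subjects) <- sprintf("%s_s%02d", group, seq_len(n_subjects))
  structure(subjects, class = "bold_cohort", planted = planted, group = group)
}

#' @export
print.planted_structure <- function(x, ...) {
  cat(sprintf("Planted structure: %d regions in %d blocks; conditions: %s\n",
              length(x$roi_labels), max(x$blocks),
              paste(names(x$sigma), collapse = ", ")))
  invisible(x)
}

#' @export
print.bold_sim <- function(x, ...) {
  cat(sprintf("Simulated BOLD run: %d scans x %d regions (TR %.2f s), %d picture trials\n",
              nrow(x$signal), ncol(x$signal), x$tr, nrow(x$amplitudes)))
  invisible(x)
}
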