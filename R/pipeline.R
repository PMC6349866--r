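#' Run configuration
#'
#' Assembles and validates the configuration of an end-to-end run.  Either
#' a simulation block is given (then all inputs are generated) or paths to
#' event/signal tables must be supplied.  The global `seed` drives every
#' stochastic stage deterministically.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global integer seed (mandatory when simulating).
#' @param simulation List of [simulate_cohort()] / [simulate_behavior()]
#'   arguments: `groups` (named list: group label -> n_subjects),
#'   `testing_means` (named list: group -> named condition means), plus
#'   optional overrides (`n_items_per_condition`, `noise_sd`, ...).
#'   `NULL` to use externally supplied inputs.
#' @param inputs List with `events` and `signals` path vectors (per
#'   subject) when `simulation` is `NULL`.
#' @param glm List: `mode` (`"lsa"`/`"lss"`), `tr`, `hrf` params list,
#'   `bandpass` (NULL or `c(low, high)`).
#' @param sweep List: `t_max`, `count`, `null_mode`, `null_reps`, `alpha`,
#'   `adjacency_threshold`.
#' @param stats List: `alpha`, `roi_error` (`"within"`/`"between"`).
#' @return Validated config list, classed `run_config`.
#' @export
run_config <- function(outdir, seed = NULL,
                       simulation = list(groups = list(day5 = 14, day15 = 13)),
                       inputs = NULL,
                       glm = list(), sweep = list(), stats = list()) {
  if (is.null(simulation) && is.null(inputs))
    stop("config needs either a simulation block or input paths")
  if (!is.null(simulation) && is.null(seed))
    stop("'seed' is mandatory when simulation is requested")
  glm_def <- list(mode = "lsa", tr = 2.5, hrf = list(), bandpass = NULL)
  sweep_def <- list(t_max = 0.6, count = 6000, null_mode = "matched",
                    null_reps = 1000, alpha = 0.01, adjacency_threshold = 0.35)
  stats_def <- list(alpha = 0.05, roi_error = "within")
  cfg <- list(outdir = outdir, seed = if (is.null(seed)) NULL else as.integer(seed),
              simulation = simulation, inputs = inputs,
              glm = utils::modifyList(glm_def, glm),
              sweep = utils::modifyList(sweep_def, sweep),
              stats = utils::modifyList(stats_def, stats))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file whose keys
#'   mirror the [run_config()] arguments.
#' @param outdir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  do.call(run_config, raw)
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2f s) %s", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0,
                  paste(c(...), collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> single-trial GLM -> connectivity ->
#' threshold sweep / adjacency export -> behavioral and region statistics,
#' writing every stage's outputs as plain-text tables under
#' `config$outdir` and returning a manifest of file checksums.  Re-running
#' with an identical config reproduces identical checksums for all
#' deterministic stages.
#'
#' @param config A [run_config()] (or a path accepted by
#'   [read_run_config()]).
#' @return Object of class `betanet_run`: list with `grand_means`,
#'   `curves`, `adjacency`, `behavior_anova`, `roi_anova`, `beta_values`,
#'   `manifest` (data frame of output files and md5 checksums), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t_all <- as.numeric(Sys.time())
  hrf <- do.call(hrf_params, config$glm$hrf)

  ## ------------------------------------------------ stage: inputs
  t0 <- as.numeric(Sys.time())
  subjects <- list()   # per subject: list(signal, events, group)
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    planted <- if (!is.null(sim$planted)) sim$planted else planted_structure()
    groups <- sim$groups
    gseed <- config$seed
    for (g in names(groups)) {
      cohort <- simulate_cohort(groups[[g]], planted = planted,
                                n_items_per_condition = sim$n_items_per_condition %||% 12,
                                n_fillers = sim$n_fillers %||% 12,
                                tr = config$glm$tr,
                                noise_sd = sim$noise_sd %||% 1,
                                hrf = hrf, group = g, seed = gseed)
      gseed <- gseed + 100000L
      for (s in names(cohort))
        subjects[[s]] <- list(signal = cohort[[s]]$signal,
                              events = cohort[[s]]$events, group = g)
    }
    tm_def <- list(day5 = c(Rc = 9.1, Rw = 8.8, Nr = 5.9),
                   day15 = c(Rc = 8.4, Rw = 5.4, Nr = 2.4))
    behav <- do.call(rbind, lapply(names(groups), function(g) {
      means <- (sim$testing_means %||% tm_def)[[g]]
      as.data.frame(simulate_behavior(groups[[g]], condition_means = means,
                                      group = g, seed = config$seed + match(g, names(groups))))
    }))
    behav <- retention_table(behav)
  } else {
    inp <- config$inputs
    if (is.null(inp$events) || is.null(inp$signals))
      stop("inputs must provide 'events' and 'signals' paths")
    for (i in seq_along(inp$signals)) {
      sig <- as.matrix(utils::read.table(inp$signals[[i]], sep = "\t",
                                         header = TRUE, check.names = FALSE))
      ev <- read_events(if (length(inp$events) == 1L) inp$events[[1L]] else inp$events[[i]])
      sid <- names(inp$signals)[i] %||% sprintf("sub%02d", i)
      subjects[[sid]] <- list(signal = sig, events = ev,
                              group = inp$groups[[i]] %||% "all")
    }
    behav <- if (!is.null(inp$behavior)) read_retention_table(inp$behavior) else NULL
  }
  stage_log("inputs", t0, sprintf("%d subjects", length(subjects)))

  ## ------------------------------------------------ stage: betas
  t0 <- as.numeric(Sys.time())
  beta_fits <- lapply(names(subjects), function(s) {
    sub <- subjects[[s]]
    n_scans <- nrow(sub$signal)
    des <- build_trial_design(sub$events, n_scans, config$glm$tr, hrf = hrf)
    bs <- fit_trial_betas(sub$signal, des, mode = config$glm$mode, subject_id = s)
    if (!is.null(config$glm$bandpass)) {
      bp <- config$glm$bandpass
      fs <- 1 / mean_trial_spacing(sub$events)
      bs$betas <- bandpass_beta_series(bs$betas, bp[[1L]], bp[[2L]],
                                       sampling_rate = fs)
    }
    bs
  })
  names(beta_fits) <- names(subjects)
  stage_log("betas", t0)

  ## ------------------------------------------------ stage: connectivity
  t0 <- as.numeric(Sys.time())
  group_of <- vapply(subjects, `[[`, character(1L), "group")
  conds <- setdiff(unique(beta_fits[[1L]]$condition), "filler")
  grand_means <- list()
  for (g in unique(group_of)) for (cc in conds) {
    zs <- lapply(beta_fits[group_of == g], function(bs)
      fisher_z(pearson_matrix(bs, cc)))
    gm <- grand_mean_matrix(zs)
    key <- paste(g, cc, sep = ".")
    grand_means[[key]] <- gm
    write_connectivity_matrix(gm, file.path(config$outdir,
                                            paste0("grand_mean_", key, ".tsv")))
  }
  stage_log("connectivity", t0, sprintf("%d grand means", length(grand_means)))

  ## ------------------------------------------------ stage: sweep
  t0 <- as.numeric(Sys.time())
  sw <- config$sweep
  curves <- list(); adjacency <- list()
  for (key in names(grand_means)) {
    curves[[key]] <- threshold_sweep(grand_means[[key]], t_max = sw$t_max,
                                     count = sw$count, null_reps = sw$null_reps,
                                     null_mode = sw$null_mode, alpha = sw$alpha,
                                     seed = config$seed %||% 1L)
    write_threshold_curve(curves[[key]],
                          file.path(config$outdir, paste0("curve_", key, ".tsv")))
    adjacency[[key]] <- adjacency_export(grand_means[[key]],
                                         threshold = sw$adjacency_threshold)
    adf <- data.frame(roi = rownames(adjacency[[key]]$adjacency),
                      adjacency[[key]]$adjacency, check.names = FALSE)
    utils::write.table(adf, file.path(config$outdir, paste0("adjacency_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage_log("sweep", t0)

  ## ------------------------------------------------ stage: stats
  t0 <- as.numeric(Sys.time())
  behavior_anova <- NULL
  if (!is.null(behav) && nrow(behav) && length(unique(behav$group)) >= 2L) {
    behavior_anova <- mixed_rm_anova(behav)
    write_retention_table(behav, file.path(config$outdir, "behavior.csv"))
    utils::write.csv(behavior_anova$effects,
                     file.path(config$outdir, "behavior_anova.csv"), row.names = FALSE)
  }
  beta_values <- list(); roi_anova <- NULL
  has_pause <- all(vapply(beta_fits, function(b) "pause" %in% rownames(b$other),
                          logical(1L)))
  if (has_pause) {
    pooling <- region_pooling_map()
    pooled_long <- list()
    for (s in names(beta_fits)) {
      bv <- roi_beta_values(beta_fits[[s]], pooling = pooling)
      beta_values[[s]] <- bv
      pl <- bv$pooled
      for (cc in conds)
        pooled_long[[paste(s, cc)]] <- data.frame(subject_id = s,
                                                  group = group_of[[s]],
                                                  region = pl$region,
                                                  condition = cc, beta = pl[[cc]],
                                                  stringsAsFactors = FALSE)
    }
    pooled_long <- do.call(rbind, c(pooled_long, make.row.names = FALSE))
    utils::write.csv(pooled_long, file.path(config$outdir, "beta_values_pooled.csv"),
                     row.names = FALSE)
    roi_anova <- lapply(split(pooled_long, pooled_long$group), roi_rm_anova,
                        error = config$stats$roi_error, alpha = config$stats$alpha)
  }
  stage_log("stats", t0)

  ## ------------------------------------------------ manifest
  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  meta <- list(package_version = as.character(utils::packageVersion("betanet")),
               seed = config$seed, n_subjects = length(subjects),
               elapsed_s = round(as.numeric(Sys.time()) - t_all, 2),
               files = manifest)
  jsonlite::write_json(meta, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(grand_means = grand_means, curves = curves,
                 adjacency = adjacency, behavior_anova = behavior_anova,
                 roi_anova = roi_anova, beta_values = beta_values,
                 manifest = manifest, config = config),
            class = "betanet_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean interval between successive picture onsets (trial-axis sampling)
mean_trial_spacing <- function(events) {
  on <- events$onset[events$event_kind %in% picture_kinds]
  if (length(on) < 2L) stop("need >= 2 picture events to define a trial axis")
  mean(diff(on))
}

#' @export
print.betanet_run <- function(x, ...) {
  cat("betanet pipeline run\n")
  cat(sprintf("  grand means: %s\n", paste(names(x$grand_means), collapse = ", ")))
  for (key in names(x$adjacency))
    cat(sprintf("  adjacency %-12s (t = %.2f): <k> = %.1f, C = %.2f\n", key,
                x$adjacency[[key]]$threshold, x$adjacency[[key]]$k_mean,
                x$adjacency[[key]]$clustering))
  if (!is.null(x$behavior_anova)) {
    cat("  behavioral ANOVA:\n")
    print(x$behavior_anova)
  }
  invisible(x)
}

#' Human-readable run report
#'
#' Writes a plain-text summary per condition and group: the adjacency
#' summary at the fixed threshold, a condensed threshold-curve table, the
#' pooled-region beta-value table and the ANOVA results.  All numbers are
#' taken from the run's stage outputs.
#'
#' @param run A `betanet_run` from [run_pipeline()].
#' @param path Output text file (default `report.txt` in the run's outdir).
#' @return `path`, invisibly.
#' @export
report <- function(run, path = file.path(run$config$outdir, "report.txt")) {
  stopifnot(inherits(run, "betanet_run"))
  if (!length(run$curves)) stop("no sweep outputs present; run the pipeline first")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("betanet run report")
  w("==================")
  for (key in names(run$curves)) {
    cv <- run$curves[[key]]
    adj <- run$adjacency[[key]]
    w("")
    w("condition %s", key)
    w("  adjacency at t = %.2f: <k> = %.2f, C = %.3f", adj$threshold,
      adj$k_mean, adj$clustering)
    idx <- unique(round(seq(1L, nrow(cv), length.out = 10L)))
    cv <- as.data.frame(cv)
    tab <- cv[idx, intersect(c("threshold", "k_mean", "clustering", "p"), names(cv))]
    writeLines(paste0("  ", utils::capture.output(print(tab, digits = 3L,
                                                        row.names = FALSE))), con)
  }
  if (!is.null(run$behavior_anova)) {
    w("")
    w("behavioral mixed RM-ANOVA")
    writeLines(paste0("  ", utils::capture.output(print(run$behavior_anova))), con)
  }
  for (g in names(run$roi_anova)) {
    w("")
    w("region ANOVA, group %s", g)
    writeLines(paste0("  ", utils::capture.output(print(run$roi_anova[[g]]))), con)
  }
  invisible(path)
}
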