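#' Event tables
#'
#' An event table describes one scan run as a data frame with columns
#' `onset` (seconds from run start), `duration` (seconds), `event_kind`
#' (`picture`, `microphone`, `filler_picture`, `filler_microphone` or
#' `pause`), `condition` (a condition label, `"filler"` for fillers, `NA`
#' for pauses) and `item_id` (integer, `NA` for pauses).  Onsets are
#' strictly increasing and events do not overlap; every (filler) picture is
#' immediately followed by its (filler) microphone event.
#'
#' @param df A data frame with the columns above.
#' @return `df` validated, classed `event_table`.
#' @export
event_table <- function(df) {
  required <- c("onset", "duration", "event_kind", "condition", "item_id")
  if (!all(required %in% names(df)))
    stop("event table needs columns: ", paste(required, collapse = ", "))
  df <- as.data.frame(df)[, required]
  if (nrow(df)) {
    if (any(diff(df$onset) <= 0)) stop("onsets must be strictly increasing")
    if (any(df$duration <= 0, na.rm = TRUE)) stop("durations must be positive")
    if (any(df$onset[-1L] < (df$onset + df$duration)[-nrow(df)] - 1e-9))
      stop("events must not overlap")
  }
  class(df) <- c("event_table", "data.frame")
  df
}

picture_kinds <- c("picture", "filler_picture")
microphone_kinds <- c("microphone", "filler_microphone")

#' Simulate an event-related testing-session design
#'
#' Builds one run of the retrieval testing design: each of the
#' `3 * n_items_per_condition` learned items appears as a 4 s picture event
#' immediately followed by a 2 s microphone (response) event; `n_fillers`
#' filler picture/microphone pairs are interleaved pseudorandomly among the
#' items.  Conditions are assigned to items pseudorandomly and balanced.
#' Inter-trial intervals are drawn from a Gaussian (`iti_mean`, `iti_sd`)
#' truncated to \[6, 10\] s by rejection.
#'
#' @param n_items_per_condition Learned items per condition (default 12).
#' @param n_fillers Number of filler trials (default 12).
#' @param iti_mean,iti_sd Inter-trial interval Gaussian parameters, seconds.
#' @param conditions Character vector of condition labels.
#' @param picture_duration,microphone_duration Event durations, seconds.
#' @param iti_range Truncation bounds for the ITI, seconds.
#' @param seed Integer seed fixing all randomness.
#' @return An [event_table()].  Attribute `run_duration` holds the run
#'   length in seconds (last offset plus a final interval).
#' @export
simulate_testing_design <- function(n_items_per_condition = 12, n_fillers = 12,
                                    iti_mean = 8, iti_sd = 1,
                                    conditions = c("Rc", "Rw", "Nr"),
                                    picture_duration = 4, microphone_duration = 2,
                                    iti_range = c(6, 10), seed = 1) {
  if (n_items_per_condition < 0 || n_fillers < 0)
    stop("trial counts must be non-negative")
  if (iti_sd < 0) stop("'iti_sd' must be non-negative")
  set.seed(as.integer(seed))

  n_items <- n_items_per_condition * length(conditions)
  n_trials <- n_items + n_fillers
  if (n_trials == 0L) {
    out <- event_table(data.frame(onset = numeric(0), duration = numeric(0),
                                  event_kind = character(0), condition = character(0),
                                  item_id = integer(0)))
    attr(out, "run_duration") <- 0
    return(out)
  }

  cond <- sample(rep(conditions, each = n_items_per_condition))
  # interleave fillers among (not before/after all) the items when possible
  slots <- if (n_items > 1L && n_fillers > 0L && n_fillers <= n_items - 1L)
    sort(sample(seq_len(n_items - 1L), n_fillers)) else NULL
  kind <- rep("item", n_trials)
  if (!is.null(slots)) {
    # insert each filler after the item whose slot it drew
    kind <- unlist(lapply(seq_len(n_items), function(i)
      c("item", rep("filler", sum(slots == i)))))
  } else if (n_fillers > 0L) {
    kind <- sample(c(rep("item", n_items), rep("filler", n_fillers)))
  }

  itis <- rtruncnorm(n_trials, iti_mean, iti_sd, iti_range[1L], iti_range[2L])

  onset <- numeric(0); duration <- numeric(0); event_kind <- character(0)
  condition <- character(0); item_id <- integer(0)
  t <- 0; ii <- 0L; fi <- 0L; k <- 0L
  for (kd in kind) {
    k <- k + 1L
    if (kd == "item") {
      ii <- ii + 1L
      onset <- c(onset, t, t + picture_duration)
      duration <- c(duration, picture_duration, microphone_duration)
      event_kind <- c(event_kind, "picture", "microphone")
      condition <- c(condition, cond[ii], cond[ii])
      item_id <- c(item_id, ii, ii)
    } else {
      fi <- fi + 1L
      onset <- c(onset, t, t + picture_duration)
      duration <- c(duration, picture_duration, microphone_duration)
      event_kind <- c(event_kind, "filler_picture", "filler_microphone")
      condition <- c(condition, "filler", "filler")
      item_id <- c(item_id, n_items + fi, n_items + fi)
    }
    t <- t + picture_duration + microphone_duration + itis[k]
  }

  out <- event_table(data.frame(onset = onset, duration = duration,
                                event_kind = event_kind, condition = condition,
                                item_id = item_id, stringsAsFactors = FALSE))
  attr(out, "run_duration") <- t
  out
}

# truncated-normal sampler by rejection; falls back to uniform when sd = 0
# would never terminate outside the bounds
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lo || mean > hi) stop("degenerate ITI outside truncation range")
    return(rep(mean, n))
  }
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    draw <- stats::rnorm(2L * (n - filled), mean, sd)
    draw <- draw[draw >= lo & draw <= hi]
    take <- min(length(draw), n - filled)
    if (take > 0L) {
      out[(filled + 1L):(filled + take)] <- draw[seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

#' Read / write event tables as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type` (the event kind), `condition`,
#' `item_id`; tab-delimited with a header row.
#'
#' @param events An [event_table()].
#' @param path File path.
#' @return `read_events` returns an [event_table()]; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "event_kind"] <- "trial_type"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(df)[names(df) == "trial_type"] <- "event_kind"
  event_table(df)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events (%d pictures, %d fillers), %.1f s\n",
              nrow(x), sum(x$event_kind == "picture"),
              sum(x$event_kind == "filler_picture"),
              if (nrow(x)) max(x$onset + x$duration) else 0))
  print(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
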