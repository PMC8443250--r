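# Trial-schedule generation for the three-day differential conditioning
# paradigm: acquisition (day 1), extinction (day 2), retrieval test plus
# reinstatement (day 3).

CS_DURATION_S <- 6
US_OFFSET_S <- 5
ITI_SUPPORT_S <- 7:11
# discrete ITI weights giving mean 7.8 s over support 7..11 s
ITI_WEIGHTS_DEFAULT <- c(0.55, 0.2, 0.15, 0.05, 0.05)

#' Construct a session schedule object
#'
#' Low-level constructor used by the `build_*()` generators. Validates the
#' protocol invariants (trial counts, reinforcement counts, CS duration,
#' ITI range) and returns a classed list.
#'
#' @param day One of `"DAY1"`, `"DAY2"`, `"DAY3"`.
#' @param events Data frame with columns `index`, `cs_type`, `reinforced`,
#'   `onset_s`, `duration_s`, `iti_s`, `context`, `phase`.
#' @param reinstatement_us_onsets_s Numeric vector of unsignalled US onsets
#'   (day 3 only; empty otherwise).
#' @param seed Integer seed the schedule was generated from (or `NA`).
#' @return An object of class `session_schedule`.
#' @export
session_schedule <- function(day, events, reinstatement_us_onsets_s = numeric(0),
                             seed = NA_integer_) {
  day <- match.arg(day, c("DAY1", "DAY2", "DAY3"))
  stopifnot(is.data.frame(events))
  needed <- c("index", "cs_type", "reinforced", "onset_s", "duration_s",
              "iti_s", "context", "phase")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    stop("events is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(events$cs_type %in% c("CS_PLUS", "CS_MINUS"))) {
    stop("cs_type must be CS_PLUS or CS_MINUS")
  }
  if (any(events$reinforced & events$cs_type != "CS_PLUS")) {
    stop("the CS- is never reinforced")
  }
  if (any(events$duration_s != CS_DURATION_S)) {
    stop("all CS durations must be ", CS_DURATION_S, " s")
  }
  if (any(events$iti_s < min(ITI_SUPPORT_S) | events$iti_s > max(ITI_SUPPORT_S))) {
    stop("ITIs must lie in [", min(ITI_SUPPORT_S), ", ", max(ITI_SUPPORT_S), "] s")
  }
  if (is.unsorted(events$onset_s, strictly = TRUE)) {
    stop("onsets must strictly increase")
  }
  structure(
    list(day = day, events = events,
         reinstatement_us_onsets_s = reinstatement_us_onsets_s,
         seed = seed),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule> ", x$day, ": ", nrow(x$events), " trials (",
      sum(x$events$cs_type == "CS_PLUS"), " CS+, ",
      sum(x$events$cs_type == "CS_MINUS"), " CS-), ",
      sum(x$events$reinforced), " reinforced", sep = "")
  if (length(x$reinstatement_us_onsets_s)) {
    cat(", ", length(x$reinstatement_us_onsets_s), " reinstatement USs", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Sample ITIs from the discrete support with the default (or supplied) weights.
sample_itis <- function(n, weights = ITI_WEIGHTS_DEFAULT) {
  stopifnot(length(weights) == length(ITI_SUPPORT_S), all(weights >= 0))
  sample(ITI_SUPPORT_S, n, replace = TRUE, prob = weights)
}

# Pseudo-random CS order with at most `max_run` consecutive trials of the
# same type. Constructive sampling with restart on dead ends.
sample_cs_order <- function(n_plus, n_minus, max_run = 2, max_tries = 1000) {
  for (try in seq_len(max_tries)) {
    left <- c(CS_PLUS = n_plus, CS_MINUS = n_minus)
    out <- character(n_plus + n_minus)
    run_type <- ""
    run_len <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      cand <- names(left)[left > 0]
      if (run_len >= max_run) cand <- setdiff(cand, run_type)
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      out[i] <- pick
      left[pick] <- left[pick] - 1L
      if (pick == run_type) run_len <- run_len + 1L else { run_type <- pick; run_len <- 1L }
    }
    if (ok) return(out)
  }
  stop("failed to sample a constrained CS order")
}

# 0/1 reinforcement assignment over the CS+ subsequence with no more than
# `max_run` consecutive reinforced trials; rejection sampling.
sample_reinforcement <- function(n_trials, n_reinforced, max_run = 3,
                                 max_tries = 100000) {
  for (try in seq_len(max_tries)) {
    x <- integer(n_trials)
    x[sample.int(n_trials, n_reinforced)] <- 1L
    r <- rle(x)
    if (max(r$lengths[r$values == 1L]) <= max_run) return(as.logical(x))
  }
  stop("failed to sample a constrained reinforcement sequence")
}

# Assemble an events data frame from per-trial vectors, computing onsets
# sequentially from `t0`.
assemble_events <- function(cs_type, reinforced, iti_s, context, phase, t0 = 0) {
  n <- length(cs_type)
  onset <- numeric(n)
  t <- t0
  for (i in seq_len(n)) {
    onset[i] <- t
    t <- t + CS_DURATION_S + iti_s[i]
  }
  data.frame(
    index = seq_len(n), cs_type = cs_type, reinforced = reinforced,
    onset_s = onset, duration_s = CS_DURATION_S, iti_s = iti_s,
    context = context, phase = phase, stringsAsFactors = FALSE
  )
}

#' Build the acquisition-day (day 1) schedule
#'
#' Six habituation trials (3 CS+, 3 CS-, none reinforced) followed by 24
#' CS+ and 24 CS- acquisition trials in context A, with exactly 18 of the
#' CS+ trials reinforced (75% partial reinforcement). The US, when present,
#' occurs 5 s after CS onset. Order is pseudo-random with at most two
#' consecutive trials of the same CS type and at most three consecutive
#' reinforced CS+ trials.
#'
#' @param seed Non-negative integer; the schedule is deterministic in it.
#' @param iti_weights Sampling weights over ITIs of 7..11 s (default gives
#'   mean 7.8 s).
#' @return A [session_schedule()] for `DAY1`.
#' @export
build_acquisition <- function(seed, iti_weights = ITI_WEIGHTS_DEFAULT) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  withr::with_seed(as.integer(seed), {
    hab_cs <- sample_cs_order(3, 3)
    acq_cs <- sample_cs_order(24, 24)
    reinf_plus <- sample_reinforcement(24, 18)
    acq_reinf <- logical(48)
    acq_reinf[acq_cs == "CS_PLUS"] <- reinf_plus
    cs <- c(hab_cs, acq_cs)
    reinf <- c(rep(FALSE, 6), acq_reinf)
    iti <- sample_itis(54, iti_weights)
    phase <- c(rep("habituation", 6), rep("acquisition", 48))
    events <- assemble_events(cs, reinf, iti, context = "A", phase = phase)
    session_schedule("DAY1", events, seed = as.integer(seed))
  })
}

#' Build the extinction-day (day 2) schedule
#'
#' 24 CS+ and 24 CS- trials in context B with no US delivered on any trial.
#'
#' @inheritParams build_acquisition
#' @return A [session_schedule()] for `DAY2`.
#' @export
build_extinction <- function(seed, iti_weights = ITI_WEIGHTS_DEFAULT) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  withr::with_seed(as.integer(seed), {
    cs <- sample_cs_order(24, 24)
    iti <- sample_itis(48, iti_weights)
    events <- assemble_events(cs, rep(FALSE, 48), iti, context = "B",
                              phase = "extinction")
    session_schedule("DAY2", events, seed = as.integer(seed))
  })
}

#' Build the retrieval/reinstatement-day (day 3) schedule
#'
#' A retrieval test of 8 unreinforced trials per CS in the mixed context,
#' followed by four unsignalled reinstatement USs (inter-US intervals
#' uniform on 10-15 s), then a reinstatement test of 16 unreinforced
#' trials per CS starting 6-10 s after the last US. No CS-contingent US is
#' ever delivered on day 3.
#'
#' @inheritParams build_acquisition
#' @param first_cs `"CS_PLUS"` or `"CS_MINUS"`: which CS opens the
#'   reinstatement test (counterbalancing hook).
#' @return A [session_schedule()] for `DAY3` with
#'   `reinstatement_us_onsets_s` filled in.
#' @export
build_day3 <- function(seed, first_cs = c("CS_PLUS", "CS_MINUS"),
                       iti_weights = ITI_WEIGHTS_DEFAULT) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  first_cs <- match.arg(first_cs)
  withr::with_seed(as.integer(seed), {
    ret_cs <- sample_cs_order(8, 8)
    ret_iti <- sample_itis(16, iti_weights)
    retrieval <- assemble_events(ret_cs, rep(FALSE, 16), ret_iti,
                                 context = "MIX", phase = "retrieval")

    # unsignalled USs after the final retrieval ITI
    t <- max(retrieval$onset_s) + CS_DURATION_S + ret_iti[16]
    us_onsets <- numeric(4)
    for (i in 1:4) {
      us_onsets[i] <- t
      t <- t + stats::runif(1, 10, 15)
    }

    # reinstatement test begins 6-10 s after the last US
    t0 <- us_onsets[4] + stats::runif(1, 6, 10)
    repeat {
      test_cs <- sample_cs_order(16, 16)
      if (test_cs[1] == first_cs) break
    }
    test_iti <- sample_itis(32, iti_weights)
    test <- assemble_events(test_cs, rep(FALSE, 32), test_iti,
                            context = "MIX", phase = "reinstatement_test",
                            t0 = t0)
    test$index <- test$index + 16L
    events <- rbind(retrieval, test)
    session_schedule("DAY3", events, reinstatement_us_onsets_s = us_onsets,
                     seed = as.integer(seed))
  })
}

#' Received outcomes for one CS stream
#'
#' Returns the per-trial binary outcome sequence RO_t for the requested CS
#' type: 1 on trials where the US was delivered with the CS, 0 otherwise.
#' Unsignalled reinstatement USs are not CS-contingent and never appear
#' here. Habituation trials are excluded by default, matching the model
#' fitting convention.
#'
#' @param schedule A [session_schedule()].
#' @param cs_type `"CS_PLUS"` or `"CS_MINUS"`.
#' @param include_habituation Keep habituation trials in the stream?
#' @return Integer vector of 0/1 outcomes, ordered by trial.
#' @export
outcomes_for_cs <- function(schedule, cs_type, include_habituation = FALSE) {
  stopifnot(inherits(schedule, "session_schedule"))
  if (!cs_type %in% c("CS_PLUS", "CS_MINUS")) {
    stop("unknown cs_type: ", cs_type)
  }
  ev <- schedule$events
  keep <- ev$cs_type == cs_type
  if (!include_habituation) keep <- keep & ev$phase != "habituation"
  as.integer(ev$reinforced[keep])
}

#' Write a schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type` (`csplus_reinforced`,
#' `csplus_omission`, `csminus`, `reinstatement_us`), `phase`, plus an
#' extra `iti` column so schedules round-trip losslessly. Missing values
#' are written as `n/a`.
#'
#' @param schedule A [session_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "session_schedule"))
  ev <- schedule$events
  trial_type <- ifelse(ev$cs_type == "CS_MINUS", "csminus",
                       ifelse(ev$reinforced, "csplus_reinforced", "csplus_omission"))
  tab <- data.frame(onset = ev$onset_s, duration = ev$duration_s,
                    trial_type = trial_type, phase = ev$phase,
                    context = ev$context, iti = ev$iti_s,
                    stringsAsFactors = FALSE)
  if (length(schedule$reinstatement_us_onsets_s)) {
    us <- data.frame(onset = schedule$reinstatement_us_onsets_s, duration = 0,
                     trial_type = "reinstatement_us", phase = "reinstatement_us",
                     context = "MIX", iti = NA_real_, stringsAsFactors = FALSE)
    tab <- rbind(tab, us)
    tab <- tab[order(tab$onset), ]
  }
  tab_out <- tab
  tab_out$iti <- ifelse(is.na(tab$iti), "n/a", format(tab$iti, trim = TRUE))
  utils::write.table(tab_out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events TSV back into a schedule
#'
#' Inverse of [write_events_tsv()]. The day is inferred from the phase
#' labels present; the generating seed is not recoverable and is set to
#' `NA`.
#'
#' @param path Path to an events TSV written by [write_events_tsv()].
#' @return A [session_schedule()].
#' @export
read_events_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                           stringsAsFactors = FALSE)
  us <- tab[tab$trial_type == "reinstatement_us", , drop = FALSE]
  cs <- tab[tab$trial_type != "reinstatement_us", , drop = FALSE]
  phases <- unique(cs$phase)
  day <- if ("acquisition" %in% phases) "DAY1"
         else if ("extinction" %in% phases) "DAY2" else "DAY3"
  events <- data.frame(
    index = seq_len(nrow(cs)),
    cs_type = ifelse(cs$trial_type == "csminus", "CS_MINUS", "CS_PLUS"),
    reinforced = cs$trial_type == "csplus_reinforced",
    onset_s = cs$onset, duration_s = cs$duration, iti_s = as.numeric(cs$iti),
    context = cs$context, phase = cs$phase, stringsAsFactors = FALSE
  )
  session_schedule(day, events, reinstatement_us_onsets_s = us$onset)
}
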