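# Trial segmentation and response classification from event logs.
#
# Classification works from logged events alone (plus the protocol constants
# carried in the log header), so it applies equally to engine output and to
# externally supplied logs in the same dialect. Response windows are the
# half-open intervals the tasks use: a poke at exactly a window end is logged
# but not scored.

state_rows <- function(ev) which(ev$event == "state")

#' Segment an event log into trials
#'
#' A trial runs from one ITI-start (`state,iti`) to the next (or to session
#' end). A trial is *complete* once it reached a classification point (reward
#' delivery or time-out entry); a final trial truncated by session end before
#' that is flagged incomplete and excluded from counts.
#'
#' @param log An `event_log`.
#' @param paradigm `"5csrtt"` or `"5cswm"`; defaults to the log's paradigm
#'   attribute. Habituation sessions have no trial structure and yield an
#'   empty list.
#' @return List of trials; each is a list with `events` (the trial's rows),
#'   `t_start_ms` and `complete`.
#' @export
segment_trials <- function(log, paradigm = attr(log, "paradigm")) {
  stopifnot(is.data.frame(log))
  if (is.null(paradigm) || is.na(paradigm)) {
    log_parse_error("paradigm unknown: pass `paradigm` explicitly")
  }
  if (paradigm == "habituation") return(list())
  if (!paradigm %in% c("5csrtt", "5cswm")) {
    log_parse_error(sprintf("unknown paradigm '%s'", paradigm))
  }
  iti_idx <- which(log$event == "state" & log$payload == "iti")
  if (!length(iti_idx)) return(list())
  end_idx <- c(iti_idx[-1L] - 1L, nrow(log))
  terminal <- if (paradigm == "5csrtt") c("reward", "timeout")
              else c("cp_reward", "timeout")
  lapply(seq_along(iti_idx), function(i) {
    ev <- log[iti_idx[i]:end_idx[i], , drop = FALSE]
    rownames(ev) <- NULL
    complete <- any(ev$event == "state" & ev$payload %in% terminal)
    list(events = ev, t_start_ms = ev$time_ms[1L], complete = complete,
         task_params = attr(log, "task_params"))
  })
}

first_or_na <- function(x) if (length(x)) x[1L] else NA_real_

#' Classify one 5-CSRTT trial
#'
#' Assigns exactly one of `correct`, `incorrect`, `premature`, `omission`
#' from the trial's events: a poke during the ITI is premature; the first
#' poke inside the response window (stimulus onset to onset + SD + LH,
#' half-open) decides correct vs incorrect; no scored poke is an omission.
#' For correct trials the response latency is stimulus onset to the correct
#' poke, and the reward latency is the correct poke to receptacle entry.
#'
#' @param trial One element of [segment_trials()] output.
#' @param task_params Named numeric protocol constants (`sd_ms`, `lh_ms`,
#'   ...); defaults to those carried by the log header. Without them the
#'   window is bounded by the observed time-out entry instead.
#' @return List with `class`, `cued_hole`, `stim_onset_ms`,
#'   `response_latency_ms`, `reward_latency_ms`, `t_start_ms`, `complete`.
#' @export
classify_5csrtt_trial <- function(trial, task_params = trial$task_params) {
  ev <- trial$events
  if (!nrow(ev) || !(ev$event[1L] == "state" && ev$payload[1L] == "iti")) {
    log_parse_error("malformed trial: no ITI start")
  }
  out <- list(class = NA_character_, cued_hole = NA_integer_,
              stim_onset_ms = NA_real_, response_latency_ms = NA_real_,
              reward_latency_ms = NA_real_, t_start_ms = trial$t_start_ms,
              complete = trial$complete)
  if (!trial$complete) return(out)

  stim <- which(ev$event == "hole_light_on")
  timeout_t <- first_or_na(ev$time_ms[ev$event == "state" &
                                        ev$payload == "timeout"])
  pokes <- ev[ev$event == "poke", , drop = FALSE]

  if (!length(stim)) {
    # trial ended before any stimulus: a poke during the ITI aborted it
    out$class <- "premature"
    return(out)
  }
  onset <- ev$time_ms[stim[1L]]
  cued <- as.integer(ev$payload[stim[1L]])
  out$cued_hole <- cued
  out$stim_onset_ms <- onset

  win_end <- if (!is.null(task_params) &&
                 all(c("sd_ms", "lh_ms") %in% names(task_params))) {
    onset + task_params[["sd_ms"]] + task_params[["lh_ms"]]
  } else if (!is.na(timeout_t)) timeout_t else Inf
  scored <- pokes[pokes$time_ms > onset & pokes$time_ms < win_end, ,
                  drop = FALSE]

  if (any(ev$event == "reward")) {
    hit <- scored[as.integer(scored$payload) == cued, , drop = FALSE]
    out$class <- "correct"
    out$response_latency_ms <- hit$time_ms[1L] - onset
    rec_in <- ev$time_ms[ev$event == "receptacle_in" &
                           ev$time_ms >= hit$time_ms[1L]]
    out$reward_latency_ms <- first_or_na(rec_in) - hit$time_ms[1L]
  } else if (nrow(scored)) {
    out$class <- "incorrect"
  } else {
    out$class <- "omission"
  }
  out
}

#' Classify one 5-CSWM (DMTP) trial
#'
#' Sample-phase outcome is `correct`, `incorrect` or `omission`; the choice
#' phase — reached only after a sample-phase correct — is `match`,
#' `nonmatch` or `omission`, else `NA` (not reached).
#'
#' @inheritParams classify_5csrtt_trial
#' @return List with `sp_class`, `cp_class`, `sample_hole`,
#'   `distractor_hole`, onsets and latencies per phase, `t_start_ms`,
#'   `complete`.
#' @export
classify_5cswm_trial <- function(trial, task_params = trial$task_params) {
  ev <- trial$events
  if (!nrow(ev) || !(ev$event[1L] == "state" && ev$payload[1L] == "iti")) {
    log_parse_error("malformed trial: no ITI start")
  }
  out <- list(sp_class = NA_character_, cp_class = NA_character_,
              sample_hole = NA_integer_, distractor_hole = NA_integer_,
              sp_onset_ms = NA_real_, cp_onset_ms = NA_real_,
              sp_response_latency_ms = NA_real_,
              cp_response_latency_ms = NA_real_,
              t_start_ms = trial$t_start_ms, complete = trial$complete)
  if (!trial$complete) return(out)

  st <- function(name) first_or_na(ev$time_ms[ev$event == "state" &
                                                ev$payload == name])
  sp_t <- st("sp_stimulus")
  pokes <- ev[ev$event == "poke", , drop = FALSE]
  phase_window <- function(onset, key, fallback_end) {
    if (!is.null(task_params) && key %in% names(task_params)) {
      onset + task_params[[key]]
    } else fallback_end
  }

  if (is.na(sp_t)) {        # aborted during the ITI (nothing scored there)
    return(out)
  }
  lights_sp <- ev[ev$event == "hole_light_on" & ev$time_ms >= sp_t, ,
                  drop = FALSE]
  sample_hole <- as.integer(lights_sp$payload[1L])
  sp_onset <- lights_sp$time_ms[1L]
  out$sample_hole <- sample_hole
  out$sp_onset_ms <- sp_onset

  sp_rew_t <- st("sp_reward")
  timeout_t <- st("timeout")
  sp_end <- phase_window(sp_onset, "sp_sd_ms",
                         if (!is.na(timeout_t)) timeout_t else Inf)
  sp_scored <- pokes[pokes$time_ms > sp_onset & pokes$time_ms < sp_end &
                       (is.na(sp_rew_t) | pokes$time_ms <= sp_rew_t), ,
                     drop = FALSE]
  if (!is.na(sp_rew_t)) {
    out$sp_class <- "correct"
    hit <- sp_scored[as.integer(sp_scored$payload) == sample_hole, ,
                     drop = FALSE]
    out$sp_response_latency_ms <- hit$time_ms[1L] - sp_onset
  } else if (nrow(sp_scored)) {
    out$sp_class <- "incorrect"
    return(out)
  } else {
    out$sp_class <- "omission"
    return(out)
  }

  cp_t <- st("cp_stimulus")
  if (is.na(cp_t)) return(out)     # truncated after SP (still complete? no)
  lights_cp <- ev[ev$event == "hole_light_on" & ev$time_ms >= cp_t, ,
                  drop = FALSE]
  cp_holes <- as.integer(lights_cp$payload[1:2])
  out$distractor_hole <- setdiff(cp_holes, sample_hole)[1L]
  cp_onset <- lights_cp$time_ms[1L]
  out$cp_onset_ms <- cp_onset

  cp_rew_t <- st("cp_reward")
  cp_timeout <- first_or_na(ev$time_ms[ev$event == "state" &
                                         ev$payload == "timeout" &
                                         ev$time_ms >= cp_t])
  cp_end <- phase_window(cp_onset, "cp_sd_ms",
                         if (!is.na(cp_timeout)) cp_timeout else Inf)
  cp_scored <- pokes[pokes$time_ms > cp_onset & pokes$time_ms < cp_end, ,
                     drop = FALSE]
  if (!is.na(cp_rew_t)) {
    out$cp_class <- "match"
    hit <- cp_scored[as.integer(cp_scored$payload) == sample_hole, ,
                     drop = FALSE]
    out$cp_response_latency_ms <- hit$time_ms[1L] - cp_onset
  } else if (nrow(cp_scored)) {
    out$cp_class <- "nonmatch"
  } else {
    out$cp_class <- "omission"
  }
  out
}

#' Trial table for a 5-CSRTT session
#'
#' Segments and classifies a log in one step.
#'
#' @param log An `event_log` from a 5-CSRTT session.
#' @return Data frame with one row per complete trial: `trial`, `class`,
#'   `cued_hole`, `t_start_ms`, `stim_onset_ms`, `response_latency_ms`,
#'   `reward_latency_ms`.
#' @export
trials_5csrtt <- function(log) {
  trials <- segment_trials(log, "5csrtt")
  cls <- lapply(trials, classify_5csrtt_trial)
  keep <- vapply(cls, function(x) isTRUE(x$complete), logical(1))
  cls <- cls[keep]
  data.frame(trial = seq_along(cls),
             class = vapply(cls, `[[`, character(1), "class"),
             cued_hole = vapply(cls, `[[`, integer(1), "cued_hole"),
             t_start_ms = vapply(cls, `[[`, numeric(1), "t_start_ms"),
             stim_onset_ms = vapply(cls, `[[`, numeric(1), "stim_onset_ms"),
             response_latency_ms = vapply(cls, `[[`, numeric(1),
                                          "response_latency_ms"),
             reward_latency_ms = vapply(cls, `[[`, numeric(1),
                                        "reward_latency_ms"),
             stringsAsFactors = FALSE)
}

#' Trial table for a 5-CSWM session
#'
#' @param log An `event_log` from a 5-CSWM session.
#' @return Data frame with one row per complete trial carrying sample- and
#'   choice-phase outcomes and latencies.
#' @export
trials_5cswm <- function(log) {
  trials <- segment_trials(log, "5cswm")
  cls <- lapply(trials, classify_5cswm_trial)
  keep <- vapply(cls, function(x) isTRUE(x$complete), logical(1))
  cls <- cls[keep]
  data.frame(trial = seq_along(cls),
             sample_hole = vapply(cls, `[[`, integer(1), "sample_hole"),
             distractor_hole = vapply(cls, `[[`, integer(1),
                                      "distractor_hole"),
             sp_class = vapply(cls, `[[`, character(1), "sp_class"),
             cp_class = vapply(cls, `[[`, character(1), "cp_class"),
             t_start_ms = vapply(cls, `[[`, numeric(1), "t_start_ms"),
             sp_onset_ms = vapply(cls, `[[`, numeric(1), "sp_onset_ms"),
             cp_onset_ms = vapply(cls, `[[`, numeric(1), "cp_onset_ms"),
             sp_response_latency_ms = vapply(cls, `[[`, numeric(1),
                                             "sp_response_latency_ms"),
             cp_response_latency_ms = vapply(cls, `[[`, numeric(1),
                                             "cp_response_latency_ms"),
             stringsAsFactors = FALSE)
}

#' Summarise a habituation session
#'
#' @param log An `event_log` from a habituation session.
#' @return One-row data frame with reward count and total dispensed volume.
#' @export
summarize_habituation <- function(log) {
  rew <- log[log$event == "reward", , drop = FALSE]
  vols <- if (nrow(rew)) {
    vapply(strsplit(rew$payload, ";", fixed = TRUE),
           function(x) as.numeric(x[1L]), numeric(1))
  } else numeric(0)
  data.frame(paradigm = "habituation",
             n_rewards = nrow(rew),
             total_reward_ul = sum(vols),
             duration_ms = attr(log, "duration_ms") %||%
               max(c(0, log$time_ms)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
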