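# Criterion-based training-stage progression.
#
# Criteria are data, not code. Only the habituation advancement rule is a
# fixed protocol constant (at least 30 rewards in each of two consecutive
# sessions); the stage 1-5 thresholds and stage parameters below are clearly
# labelled placeholders shipped as an editable schedule, since labs tune
# these values per cohort.

#' Per-stage advancement criteria
#'
#' A stage is passed when the trailing `n_consecutive` sessions each meet
#' every non-NA threshold.
#'
#' @param min_accuracy Minimum accuracy (%) per session, or NA (unused).
#' @param max_pct_omissions Maximum omission rate (%) per session, or NA.
#' @param min_correct Minimum number of correct responses per session, or NA.
#' @param min_rewards Minimum number of rewards per session, or NA
#'   (habituation's criterion).
#' @param n_consecutive Number of consecutive sessions that must meet all
#'   thresholds (>= 1).
#' @return A `stage_criteria` object.
#' @examples
#' stage_criteria(min_rewards = 30, n_consecutive = 2)  # habituation rule
#' @export
stage_criteria <- function(min_accuracy = NA, max_pct_omissions = NA,
                           min_correct = NA, min_rewards = NA,
                           n_consecutive = 1L) {
  if (!is.numeric(n_consecutive) || n_consecutive < 1) {
    config_error("`n_consecutive` must be >= 1")
  }
  structure(list(min_accuracy = as.numeric(min_accuracy),
                 max_pct_omissions = as.numeric(max_pct_omissions),
                 min_correct = as.numeric(min_correct),
                 min_rewards = as.numeric(min_rewards),
                 n_consecutive = as.integer(n_consecutive)),
            class = "stage_criteria")
}

criterion_columns <- c(min_accuracy = "accuracy",
                       max_pct_omissions = "pct_omissions",
                       min_correct = "n_correct",
                       min_rewards = "n_rewards")

session_meets <- function(row, criteria) {
  for (crit in names(criterion_columns)) {
    thr <- criteria[[crit]]
    if (is.na(thr)) next
    col <- criterion_columns[[crit]]
    if (!col %in% names(row)) {
      config_error(sprintf("criterion needs metric '%s' missing from history",
                           col))
    }
    val <- row[[col]]
    if (is.na(val)) return(FALSE)
    ok <- switch(crit,
                 min_accuracy = val >= thr,
                 max_pct_omissions = val <= thr,
                 min_correct = val >= thr,
                 min_rewards = val >= thr)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Decide whether a subject advances to the next training stage
#'
#' Advances iff the last `n_consecutive` sessions of the history each meet
#' all thresholds of the stage's criteria. The decision depends only on the
#' trailing `n_consecutive` sessions.
#'
#' @param history Data frame of session summaries for the current stage, in
#'   chronological order (e.g. stacked [compute_5csrtt_metrics()] rows or a
#'   [read_summary_csv()] table).
#' @param criteria A [stage_criteria()] object.
#' @return List with `advance` (logical), `streak` (current run of
#'   criterion-meeting sessions) and `needed` (`n_consecutive`).
#' @examples
#' h <- data.frame(n_rewards = c(29, 30, 30))
#' evaluate_transition(h, stage_criteria(min_rewards = 30,
#'                                       n_consecutive = 2))$advance  # TRUE
#' @export
evaluate_transition <- function(history, criteria) {
  stopifnot(is.data.frame(history), inherits(criteria, "stage_criteria"))
  if (!nrow(history)) config_error("history must contain >= 1 session")
  k <- criteria$n_consecutive
  meets <- vapply(seq_len(nrow(history)),
                  function(i) session_meets(history[i, , drop = FALSE],
                                            criteria),
                  logical(1))
  streak <- 0L
  for (m in rev(meets)) {
    if (!m) break
    streak <- streak + 1L
  }
  list(advance = streak >= k, streak = min(streak, k), needed = k)
}

#' Default training schedule (habituation then 5-CSRTT stages 1-5)
#'
#' Habituation carries the standard advancement rule (>= 30 rewards in two
#' consecutive sessions). Stage parameters ramp the stimulus duration down to
#' the 2 s SD / 5 s ITI baseline of stage 5; the intermediate SD/ITI values
#' and all stage criteria are editable placeholders.
#'
#' @return Named list of stages; each has `name`, `paradigm`, `params` and
#'   `criteria`.
#' @export
default_training_schedule <- function() {
  crit <- function(...) stage_criteria(..., n_consecutive = 2L)
  list(
    habituation = list(name = "habituation", paradigm = "habituation",
                       params = habituation_params(),
                       criteria = crit(min_rewards = 30)),
    stage1 = list(name = "stage1", paradigm = "5csrtt",
                  params = fivecsrtt_params(sd_ms = 20000, iti_ms = 2000),
                  criteria = crit(min_correct = 30)),
    stage2 = list(name = "stage2", paradigm = "5csrtt",
                  params = fivecsrtt_params(sd_ms = 8000, iti_ms = 5000),
                  criteria = crit(min_correct = 30, min_accuracy = 40)),
    stage3 = list(name = "stage3", paradigm = "5csrtt",
                  params = fivecsrtt_params(sd_ms = 4000, iti_ms = 5000),
                  criteria = crit(min_correct = 30, min_accuracy = 60,
                                  max_pct_omissions = 50)),
    stage4 = list(name = "stage4", paradigm = "5csrtt",
                  params = fivecsrtt_params(sd_ms = 3000, iti_ms = 5000),
                  criteria = crit(min_correct = 30, min_accuracy = 80,
                                  max_pct_omissions = 50)),
    stage5 = list(name = "stage5", paradigm = "5csrtt",
                  params = fivecsrtt_params(sd_ms = 2000, iti_ms = 5000),
                  criteria = crit(min_correct = 30, min_accuracy = 80,
                                  max_pct_omissions = 50))
  )
}

build_stage_task <- function(stage) {
  switch(stage$paradigm,
         habituation = build_habituation(stage$params),
         `5csrtt` = build_5csrtt(stage$params),
         `5cswm` = build_5cswm(stage$params),
         config_error(sprintf("unknown paradigm '%s'", stage$paradigm)))
}

#' Simulate a subject's training trajectory through a schedule
#'
#' Runs daily sessions with the given virtual subject, applies
#' [evaluate_transition()] after each, and advances stages until the
#' schedule completes or `max_sessions` is exhausted (in which case the
#' trajectory is marked incomplete). Stages are never skipped.
#'
#' @param agent_parameters An [agent_params()] object driving every session.
#' @param schedule A schedule as from [default_training_schedule()].
#' @param max_sessions Cap on total sessions.
#' @param seed Base seed; session `i` uses `seed + i`.
#' @param session_duration_ms Duration of each simulated session.
#' @return List with `trajectory` (one row per session: stage, key metrics,
#'   advancement flag), `sessions_per_stage`, and `completed`.
#' @export
run_training_simulation <- function(agent_parameters = agent_params(),
                                    schedule = default_training_schedule(),
                                    max_sessions = 50L, seed = 1L,
                                    session_duration_ms = 30L * 60L * 1000L) {
  agent <- stochastic_agent(agent_parameters)
  stage_i <- 1L
  history <- NULL
  rows <- list()
  session <- 0L
  while (stage_i <= length(schedule) && session < max_sessions) {
    session <- session + 1L
    stage <- schedule[[stage_i]]
    task <- build_stage_task(stage)
    log <- run_session(task, agent, seed = seed + session,
                       duration_ms = session_duration_ms)
    summ <- switch(stage$paradigm,
                   habituation = summarize_habituation(log),
                   `5csrtt` = compute_5csrtt_metrics(
                     trials_5csrtt(log),
                     duration_ms = attr(log, "duration_ms"),
                     stage = stage$name),
                   `5cswm` = compute_5cswm_metrics(
                     trials_5cswm(log),
                     duration_ms = attr(log, "duration_ms"),
                     stage = stage$name))
    history <- if (is.null(history)) as.data.frame(summ)
               else rbind(history, as.data.frame(summ))
    dec <- evaluate_transition(history, stage$criteria)
    rows[[session]] <- data.frame(
      session = session, stage = stage$name,
      n_rewards = if ("n_rewards" %in% names(summ)) summ$n_rewards else NA,
      n_correct = if ("n_correct" %in% names(summ)) summ$n_correct else NA,
      accuracy = if ("accuracy" %in% names(summ)) summ$accuracy else NA,
      pct_omissions = if ("pct_omissions" %in% names(summ)) {
        summ$pct_omissions
      } else NA,
      advanced = dec$advance, stringsAsFactors = FALSE)
    if (dec$advance) {
      stage_i <- stage_i + 1L
      history <- NULL
    }
  }
  trajectory <- do.call(rbind, rows)
  sessions_per_stage <- if (!is.null(trajectory)) {
    tab <- table(factor(trajectory$stage,
                        levels = vapply(schedule, `[[`, character(1),
                                        "name")))
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(trajectory = trajectory,
       sessions_per_stage = sessions_per_stage,
       completed = stage_i > length(schedule))
}
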