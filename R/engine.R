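# Discrete-event runtime for virtual operant boxes.
#
# Time base: integer milliseconds since session start (t = 0 at the
# session_start event); there is no wall-clock dependence. All pending work
# lives in one event queue holding subject inputs (pokes, receptacle
# entries/exits) and named timers. Simultaneity tie-break: at equal
# timestamps, subject inputs are processed before timer expiries; among
# inputs, insertion order; among timers, alphabetically by timer name. This
# makes a session a pure function of (task, agent, seed, duration).

EVENT_CLASS_INPUT <- 0L
EVENT_CLASS_TIMER <- 1L

engine_fault <- function(msg) {
  stop(errorCondition(msg, class = c("fivechoice_engine_fault", "error")))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("fivechoice_config_error", "error")))
}

# ---- pump ----------------------------------------------------------------

#' Pump calibration
#'
#' Maps commanded liquid volumes to stepper-motor steps. Volumes are coded as
#' a number of motor steps; the calibration constant is the volume moved per
#' step. The default of 0.5 microlitres/step is a configurable placeholder:
#' real pumps are calibrated empirically.
#'
#' @param ul_per_step Positive volume (microlitres) delivered per motor step.
#' @return An object of class `pump_calibration`.
#' @seealso [volume_to_steps()]
#' @export
pump_calibration <- function(ul_per_step = 0.5) {
  if (!is.numeric(ul_per_step) || length(ul_per_step) != 1L || ul_per_step <= 0) {
    config_error("`ul_per_step` must be a single positive number")
  }
  structure(list(ul_per_step = as.numeric(ul_per_step)),
            class = "pump_calibration")
}

#' Convert a reward volume to motor steps
#'
#' Nearest-step rule: `steps = round(volume / ul_per_step)` (exact halves
#' follow R's round-half-to-even). The delivered volume therefore differs from
#' the commanded volume by at most half a step's volume.
#'
#' @param volume_ul Commanded volume in microlitres (>= 0).
#' @param calibration A [pump_calibration()] object.
#' @return Integer number of steps.
#' @examples
#' volume_to_steps(20, pump_calibration(0.5))  # 40
#' volume_to_steps(20, pump_calibration(0.7))  # 29
#' @export
volume_to_steps <- function(volume_ul, calibration = pump_calibration()) {
  stopifnot(inherits(calibration, "pump_calibration"))
  if (!is.numeric(volume_ul) || length(volume_ul) != 1L || is.na(volume_ul)) {
    config_error("`volume_ul` must be a single number")
  }
  if (volume_ul < 0) config_error("`volume_ul` must be non-negative")
  as.integer(round(volume_ul / calibration$ul_per_step))
}

# ---- engine context ------------------------------------------------------

new_engine_context <- function(task, agent, seed, duration_ms, max_trials,
                               calibration) {
  ctx <- new.env(parent = emptyenv())
  ctx$machine <- task
  ctx$agent <- agent
  ctx$now <- 0L
  ctx$duration <- as.integer(duration_ms)
  ctx$max_trials <- max_trials
  ctx$trials_started <- 0L
  ctx$state <- NA_character_
  ctx$done <- FALSE
  ctx$calibration <- calibration

  # device state
  ctx$hole_lights <- rep(FALSE, 5L)
  ctx$house_light <- FALSE
  ctx$receptacle_light <- FALSE
  ctx$ttl <- rep(FALSE, 4L)
  ctx$n_rewards <- 0L
  ctx$total_reward_ul <- 0

  # per-state deadlines handlers may consult (half-open response windows)
  ctx$deadline <- NA_real_

  # RNG streams: task randomness and agent behaviour are independent
  ctx$rng_task <- new_rng_stream(seed)
  ctx$rng_agent <- new_rng_stream(seed + 10000L)
  ctx$agent_mem <- new.env(parent = emptyenv())

  # event queue (parallel vectors, swap-remove on pop; stays small)
  n0 <- 64L
  ctx$q_time <- numeric(n0)
  ctx$q_class <- integer(n0)
  ctx$q_name <- character(n0)
  ctx$q_hole <- integer(n0)
  ctx$q_agent <- logical(n0)   # TRUE for cancellable agent-planned inputs
  ctx$q_seq <- integer(n0)
  ctx$q_n <- 0L
  ctx$q_next_seq <- 0L

  # log buffer (parallel vectors, doubling)
  m0 <- 1024L
  ctx$log_time <- integer(m0)
  ctx$log_event <- character(m0)
  ctx$log_payload <- character(m0)
  ctx$log_n <- 0L
  ctx
}

queue_push <- function(ctx, time, class, name, hole = NA_integer_,
                       agent = FALSE) {
  if (time < ctx$now) {
    engine_fault(sprintf("event '%s' scheduled in the past (%d < %d)",
                         name, as.integer(time), ctx$now))
  }
  n <- ctx$q_n + 1L
  if (n > length(ctx$q_time)) {
    grow <- function(x) c(x, x)   # double capacity
    ctx$q_time <- grow(ctx$q_time); ctx$q_class <- grow(ctx$q_class)
    ctx$q_name <- grow(ctx$q_name); ctx$q_hole <- grow(ctx$q_hole)
    ctx$q_agent <- grow(ctx$q_agent); ctx$q_seq <- grow(ctx$q_seq)
  }
  ctx$q_time[n] <- time
  ctx$q_class[n] <- class
  ctx$q_name[n] <- name
  ctx$q_hole[n] <- hole
  ctx$q_agent[n] <- agent
  ctx$q_seq[n] <- ctx$q_next_seq
  ctx$q_next_seq <- ctx$q_next_seq + 1L
  ctx$q_n <- n
  invisible(NULL)
}

queue_drop <- function(ctx, idx) {
  # swap-remove (order irrelevant: pop scans for the minimum)
  for (i in sort(idx, decreasing = TRUE)) {
    n <- ctx$q_n
    if (i != n) {
      ctx$q_time[i] <- ctx$q_time[n]; ctx$q_class[i] <- ctx$q_class[n]
      ctx$q_name[i] <- ctx$q_name[n]; ctx$q_hole[i] <- ctx$q_hole[n]
      ctx$q_agent[i] <- ctx$q_agent[n]; ctx$q_seq[i] <- ctx$q_seq[n]
    }
    ctx$q_n <- n - 1L
  }
  invisible(NULL)
}

queue_pop <- function(ctx) {
  n <- ctx$q_n
  if (n == 0L) return(NULL)
  idx <- seq_len(n)
  # order: time, then inputs before timers, then timer name, then insertion
  key_name <- ifelse(ctx$q_class[idx] == EVENT_CLASS_TIMER, ctx$q_name[idx], "")
  best <- idx[order(ctx$q_time[idx], ctx$q_class[idx], key_name,
                    ctx$q_seq[idx])][1L]
  ev <- list(time = ctx$q_time[best], class = ctx$q_class[best],
             name = ctx$q_name[best], hole = ctx$q_hole[best])
  queue_drop(ctx, best)
  ev
}

cancel_timer <- function(ctx, name) {
  idx <- which(seq_len(ctx$q_n) > 0L &
                 ctx$q_class[seq_len(ctx$q_n)] == EVENT_CLASS_TIMER &
                 ctx$q_name[seq_len(ctx$q_n)] == name)
  if (length(idx)) queue_drop(ctx, idx)
  invisible(NULL)
}

cancel_agent_inputs <- function(ctx) {
  idx <- which(ctx$q_agent[seq_len(ctx$q_n)])
  if (length(idx)) queue_drop(ctx, idx)
  invisible(NULL)
}

cancel_transient_timers <- function(ctx) {
  # on state exit all timers die unless declared persistent
  keep <- ctx$machine$persistent_timers
  idx <- seq_len(ctx$q_n)
  drop <- idx[ctx$q_class[idx] == EVENT_CLASS_TIMER &
                !(ctx$q_name[idx] %in% keep)]
  if (length(drop)) queue_drop(ctx, drop)
  invisible(NULL)
}

set_timer <- function(ctx, name, delay_ms) {
  if (is.na(delay_ms) || delay_ms < 0) {
    engine_fault(sprintf("negative or missing delay for timer '%s'", name))
  }
  queue_push(ctx, ctx$now + round(delay_ms), EVENT_CLASS_TIMER, name)
}

# ---- logging and devices -------------------------------------------------

log_event <- function(ctx, event, payload = "") {
  n <- ctx$log_n + 1L
  if (n > length(ctx$log_time)) {
    ctx$log_time <- c(ctx$log_time, ctx$log_time)
    ctx$log_event <- c(ctx$log_event, ctx$log_event)
    ctx$log_payload <- c(ctx$log_payload, ctx$log_payload)
  }
  ctx$log_time[n] <- ctx$now
  ctx$log_event[n] <- event
  ctx$log_payload[n] <- as.character(payload)
  ctx$log_n <- n
  invisible(NULL)
}

set_hole_light <- function(ctx, hole, on) {
  hole <- as.integer(hole)
  if (hole < 1L || hole > 5L) engine_fault("hole index out of 1..5")
  if (ctx$hole_lights[hole] != on) {
    ctx$hole_lights[hole] <- on
    log_event(ctx, if (on) "hole_light_on" else "hole_light_off", hole)
  }
  invisible(NULL)
}

set_house_light <- function(ctx, on) {
  if (ctx$house_light != on) {
    ctx$house_light <- on
    log_event(ctx, if (on) "house_light_on" else "house_light_off")
  }
  invisible(NULL)
}

set_receptacle_light <- function(ctx, on) {
  if (ctx$receptacle_light != on) {
    ctx$receptacle_light <- on
    log_event(ctx, if (on) "receptacle_light_on" else "receptacle_light_off")
  }
  invisible(NULL)
}

set_ttl <- function(ctx, channel, level) {
  channel <- as.integer(channel)
  if (channel < 1L || channel > length(ctx$ttl)) {
    config_error(sprintf("TTL channel %d out of range 1..%d",
                         channel, length(ctx$ttl)))
  }
  if (ctx$ttl[channel] != level) {
    ctx$ttl[channel] <- level
    log_event(ctx, if (level) "ttl_high" else "ttl_low", channel)
  }
  invisible(NULL)
}

dispense_reward <- function(ctx, volume_ul) {
  steps <- volume_to_steps(volume_ul, ctx$calibration)
  log_event(ctx, "reward", sprintf("%g;%d", volume_ul, steps))
  ctx$n_rewards <- ctx$n_rewards + 1L
  ctx$total_reward_ul <- ctx$total_reward_ul + volume_ul
  invisible(NULL)
}

all_devices_off <- function(ctx) {
  for (h in which(ctx$hole_lights)) set_hole_light(ctx, h, FALSE)
  set_receptacle_light(ctx, FALSE)
  set_house_light(ctx, FALSE)
  for (ch in which(ctx$ttl)) set_ttl(ctx, ch, FALSE)
  invisible(NULL)
}

end_session <- function(ctx) {
  if (ctx$done) return(invisible(NULL))
  all_devices_off(ctx)
  log_event(ctx, "session_end")
  ctx$done <- TRUE
  invisible(NULL)
}

# ---- state machine -------------------------------------------------------

enter_state <- function(ctx, state) {
  machine <- ctx$machine
  if (!state %in% machine$states) {
    engine_fault(sprintf("unknown state '%s'", state))
  }
  cancel_transient_timers(ctx)
  ctx$deadline <- NA_real_
  ctx$state <- state
  log_event(ctx, "state", state)
  on_enter <- machine$on_enter[[state]]
  if (!is.null(on_enter)) on_enter(ctx)
  invisible(NULL)
}

# Cue notifications go to any attached opto/TTL schedules and to the agent.
notify <- function(ctx, cue, data = list()) {
  for (sched in ctx$machine$opto) {
    if (identical(sched$cue, cue)) {
      if (sched$onset_offset_ms == 0) {
        set_ttl(ctx, sched$channel, TRUE)
      } else {
        set_timer(ctx, sprintf("opto%d_high", sched$channel),
                  sched$onset_offset_ms)
      }
      set_timer(ctx, sprintf("opto%d_low", sched$channel),
                sched$onset_offset_ms + sched$pulse_ms)
    }
  }
  agent <- ctx$agent
  if (!is.null(agent$handle)) {
    reply <- with_stream(ctx$rng_agent,
                         agent$handle(ctx$agent_mem, cue, data, ctx$now))
    if (!is.null(reply)) {
      if (isTRUE(reply$cancel)) cancel_agent_inputs(ctx)
      acts <- reply$actions
      if (!is.null(acts) && nrow(acts)) {
        for (i in seq_len(nrow(acts))) {
          queue_push(ctx, max(ctx$now, round(acts$time[i])),
                     EVENT_CLASS_INPUT, acts$action[i],
                     hole = if ("hole" %in% names(acts)) {
                       as.integer(acts$hole[i])
                     } else NA_integer_,
                     agent = TRUE)
        }
      }
    }
  }
  invisible(NULL)
}

#' Process one event against the running session context
#'
#' Advances the virtual clock to the event time, logs subject inputs, and
#' invokes the handler declared for the current (state, event) pair. A pair
#' with no handler and no declared ignore raises an engine fault naming the
#' pair; an event timed before the current clock also faults.
#'
#' Used internally by [run_session()]; exposed for single-stepping a machine
#' in tests or interactive exploration.
#'
#' @param ctx An engine context (see [run_session()]).
#' @param event List with `time` (ms), `class` (0 input, 1 timer), `name`,
#'   and optionally `hole`.
#' @return The context, invisibly.
#' @keywords internal
#' @export
dispatch_event <- function(ctx, event) {
  if (event$time < ctx$now) {
    engine_fault(sprintf("event '%s' from the past (%d < %d)",
                         event$name, as.integer(event$time), ctx$now))
  }
  ctx$now <- as.integer(event$time)
  machine <- ctx$machine
  is_input <- event$class == EVENT_CLASS_INPUT
  if (is_input) {
    # every subject input is logged, whatever the task makes of it
    log_event(ctx, event$name,
              if (is.na(event$hole)) "" else event$hole)
  }
  handler <- machine$handlers[[ctx$state]][[event$name]]
  if (is.null(handler) && !is_input) {
    handler <- machine$global_handlers[[event$name]]
  }
  if (!is.null(handler)) {
    handler(ctx, ctx$now, event$hole)
  } else {
    ignored <- event$name %in% machine$ignore[[ctx$state]] ||
      (is_input && isTRUE(machine$ignore_inputs_default))
    if (!ignored) {
      engine_fault(sprintf("no handler for event '%s' in state '%s'",
                           event$name, ctx$state))
    }
  }
  invisible(ctx)
}

# ---- session runner ------------------------------------------------------

#' Run one simulated operant session
#'
#' Executes a task state machine against a virtual subject on a millisecond
#' discrete-event clock, producing the complete time-sorted event log.
#' Identical `(task, agent, seed, duration_ms, max_trials)` yield a
#' byte-identical log.
#'
#' @param task A task machine from [build_5csrtt()], [build_habituation()] or
#'   [build_5cswm()].
#' @param agent A virtual subject from [stochastic_agent()] or
#'   [scripted_agent()].
#' @param seed Integer seed; the engine and the agent derive independent
#'   RNG streams from it.
#' @param duration_ms Session duration in ms (default 30 min, the standard
#'   daily session length).
#' @param max_trials Optional cap on the number of started trials; the session
#'   ends early once the cap is reached (useful for fixed-trial-count
#'   simulations). `Inf` (default) runs to `duration_ms`.
#' @param calibration [pump_calibration()] used for reward step coding.
#' @return An `event_log`: a data.frame with columns `time_ms`, `event`,
#'   `payload`, carrying the paradigm, seed, duration and task parameters as
#'   attributes.
#' @examples
#' task <- build_5csrtt(fivecsrtt_params())
#' agent <- stochastic_agent(agent_params(p_respond = 1, p_correct = 1,
#'                                        premature_hazard = 0))
#' log <- run_session(task, agent, seed = 1, duration_ms = 120000)
#' head(log)
#' @export
run_session <- function(task, agent, seed = 1L,
                        duration_ms = 30L * 60L * 1000L,
                        max_trials = Inf,
                        calibration = pump_calibration()) {
  stopifnot(inherits(task, "fc_task"), inherits(agent, "fc_agent"))
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    config_error("`duration_ms` must be positive")
  }
  if (is.null(task$initial) || !task$initial %in% task$states) {
    config_error("task has no valid initial state")
  }
  ctx <- new_engine_context(task, agent, seed, duration_ms, max_trials,
                            calibration)
  log_event(ctx, "session_start")
  set_timer(ctx, "session_end", ctx$duration)
  if (!is.null(agent$init)) with_stream(ctx$rng_agent, agent$init(ctx))
  if (!is.null(task$on_start)) task$on_start(ctx)
  enter_state(ctx, task$initial)

  while (!ctx$done) {
    ev <- queue_pop(ctx)
    if (is.null(ev)) {
      # nothing left to happen; jump to session end
      ctx$now <- ctx$duration
      end_session(ctx)
      break
    }
    if (ev$time >= ctx$duration &&
        !(ev$class == EVENT_CLASS_TIMER && ev$name == "session_end")) {
      # beyond the session: drop; the session_end timer is still queued
      next
    }
    if (ev$class == EVENT_CLASS_TIMER && ev$name == "session_end") {
      ctx$now <- ctx$duration
      end_session(ctx)
      break
    }
    dispatch_event(ctx, ev)
  }

  n <- ctx$log_n
  out <- data.frame(time_ms = ctx$log_time[seq_len(n)],
                    event = ctx$log_event[seq_len(n)],
                    payload = ctx$log_payload[seq_len(n)],
                    stringsAsFactors = FALSE)
  new_event_log(out,
                paradigm = task$paradigm,
                seed = as.integer(seed),
                duration_ms = ctx$now,
                task_params = task$param_record,
                engine_counts = list(n_rewards = ctx$n_rewards,
                                     total_reward_ul = ctx$total_reward_ul,
                                     trials_started = ctx$trials_started))
}

# Called by task builders at ITI entry: enforces the trial cap.
note_trial_start <- function(ctx) {
  if (ctx$trials_started >= ctx$max_trials) {
    end_session(ctx)
    return(FALSE)
  }
  ctx$trials_started <- ctx$trials_started + 1L
  TRUE
}
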