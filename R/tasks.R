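# Task builders: each returns an `fc_task` state machine the engine can run.
#
# Response windows are half-open [start, end): a poke at exactly the stimulus
# end still falls in the limited hold, a poke at exactly the limited-hold end
# is logged but no longer scored (it becomes an omission). Handlers enforce
# this with stored deadlines, independent of queue tie-breaking.

new_task <- function(paradigm, states, initial, params, param_record,
                     on_start = NULL, on_enter = list(), handlers = list(),
                     cues = character()) {
  structure(list(paradigm = paradigm,
                 states = states,
                 initial = initial,
                 params = params,
                 param_record = param_record,
                 on_start = on_start,
                 on_enter = on_enter,
                 handlers = handlers,
                 global_handlers = list(),
                 ignore = list(),
                 ignore_inputs_default = TRUE,
                 persistent_timers = "session_end",
                 cues = cues,
                 opto = list()),
            class = "fc_task")
}

#' @export
print.fc_task <- function(x, ...) {
  cat(sprintf("<fc_task: %s>\n", x$paradigm))
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  pr <- x$param_record
  cat("  params:", paste(sprintf("%s=%g", names(pr), pr), collapse = ", "),
      "\n")
  if (length(x$opto)) {
    cat(sprintf("  opto schedules: %d\n", length(x$opto)))
  }
  invisible(x)
}

# ---- 5-CSRTT -------------------------------------------------------------

#' Build the 5-choice serial reaction time task
#'
#' Operant cycle: an inter-trial interval (started at session start, at
#' receptacle exit after reward collection, or at time-out end) is followed by
#' illumination of one pseudo-randomly chosen hole for the stimulus duration,
#' then a limited-hold window with the light off. A poke into the cued hole
#' during stimulus or limited hold is a *correct* response: the stimulus is
#' extinguished immediately and the reward is delivered at the illuminated
#' receptacle. A poke into any hole during the ITI (*premature*), into a
#' non-cued hole during the response window (*incorrect*), or no poke at all
#' (*omission*) terminates the trial immediately with a time-out during which
#' the house light — otherwise on — is switched off.
#'
#' @param params A [fivecsrtt_params()] object.
#' @return An `fc_task` machine for [run_session()].
#' @export
build_5csrtt <- function(params = fivecsrtt_params()) {
  stopifnot(inherits(params, "fivecsrtt_params"))
  p <- params

  pick_iti <- function(ctx) {
    if (is.null(p$iti_set)) return(p$iti_ms)
    with_stream(ctx$rng_task,
                p$iti_set[sample.int(length(p$iti_set), 1L)])
  }

  start_reward <- function(ctx) {
    set_hole_light(ctx, ctx$cued_hole, FALSE)  # immediate feedback
    enter_state(ctx, "reward")
  }

  on_enter <- list(
    iti = function(ctx) {
      if (!note_trial_start(ctx)) return(invisible(NULL))
      iti <- pick_iti(ctx)
      ctx$deadline <- ctx$now + iti
      set_timer(ctx, "iti_end", iti)
      notify(ctx, "iti_start", list(iti_ms = iti))
    },
    stimulus = function(ctx) {
      set_hole_light(ctx, ctx$cued_hole, TRUE)
      ctx$win_end <- ctx$now + p$sd_ms + p$lh_ms
      set_timer(ctx, "sd_end", p$sd_ms)
      notify(ctx, "stimulus_on",
             list(target = ctx$cued_hole,
                  alternatives = setdiff(1:5, ctx$cued_hole),
                  window_ms = p$sd_ms + p$lh_ms))
    },
    limited_hold = function(ctx) {
      set_timer(ctx, "lh_end", p$lh_ms)
    },
    reward = function(ctx) {
      dispense_reward(ctx, p$reward_ul)
      set_receptacle_light(ctx, TRUE)
      notify(ctx, "reward_available", list())
    },
    timeout = function(ctx) {
      for (h in which(ctx$hole_lights)) set_hole_light(ctx, h, FALSE)
      set_house_light(ctx, FALSE)
      set_timer(ctx, "timeout_end", p$timeout_ms)
      notify(ctx, "timeout_start", list())
    })

  handlers <- list(
    iti = list(
      poke = function(ctx, time, hole) {
        if (time >= ctx$deadline) return(invisible(NULL))  # stimulus imminent
        enter_state(ctx, "timeout")                        # premature
      },
      iti_end = function(ctx, time, hole) {
        ctx$cued_hole <- with_stream(ctx$rng_task, sample.int(5L, 1L))
        enter_state(ctx, "stimulus")
      }),
    stimulus = list(
      poke = function(ctx, time, hole) {
        if (hole == ctx$cued_hole) start_reward(ctx)
        else enter_state(ctx, "timeout")                   # incorrect
      },
      sd_end = function(ctx, time, hole) {
        set_hole_light(ctx, ctx$cued_hole, FALSE)
        enter_state(ctx, "limited_hold")
      }),
    limited_hold = list(
      poke = function(ctx, time, hole) {
        if (time >= ctx$win_end) return(invisible(NULL))   # window closed
        if (hole == ctx$cued_hole) start_reward(ctx)
        else enter_state(ctx, "timeout")
      },
      lh_end = function(ctx, time, hole) {
        enter_state(ctx, "timeout")                        # omission
      }),
    reward = list(
      receptacle_in = function(ctx, time, hole) {
        notify(ctx, "reward_collected", list())
      },
      receptacle_out = function(ctx, time, hole) {
        set_receptacle_light(ctx, FALSE)
        enter_state(ctx, "iti")
      }),
    timeout = list(
      timeout_end = function(ctx, time, hole) {
        set_house_light(ctx, TRUE)
        enter_state(ctx, "iti")
      })
  )

  rec <- c(sd_ms = p$sd_ms, iti_ms = p$iti_ms, lh_ms = p$lh_ms,
           timeout_ms = p$timeout_ms, reward_ul = p$reward_ul)
  if (!is.null(p$iti_set)) {
    rec <- c(rec, stats::setNames(p$iti_set,
                                  paste0("iti_set", seq_along(p$iti_set))))
  }
  new_task("5csrtt",
           states = c("iti", "stimulus", "limited_hold", "reward", "timeout"),
           initial = "iti", params = p, param_record = rec,
           on_start = function(ctx) set_house_light(ctx, TRUE),
           on_enter = on_enter, handlers = handlers,
           cues = c("iti_start", "stimulus_on", "reward_available",
                    "reward_collected", "timeout_start"))
}

# ---- habituation ---------------------------------------------------------

#' Build the habituation training task
#'
#' All five holes of the 5-choice wall are illuminated for an unlimited time;
#' a poke into any of them earns the reward at the illuminated receptacle.
#' Receptacle exit re-arms the cycle. The standard advancement rule (at least
#' 30 rewards in each of two consecutive sessions) lives in the scheduler, see
#' [default_training_schedule()].
#'
#' @param params A [habituation_params()] object.
#' @return An `fc_task` machine for [run_session()].
#' @export
build_habituation <- function(params = habituation_params()) {
  stopifnot(inherits(params, "habituation_params"))
  p <- params

  on_enter <- list(
    active = function(ctx) {
      for (h in 1:5) set_hole_light(ctx, h, TRUE)  # unlimited illumination
      notify(ctx, "stimulus_on",
             list(target = NA_integer_, alternatives = 1:5,
                  window_ms = Inf))
    },
    reward = function(ctx) {
      dispense_reward(ctx, p$reward_ul)
      set_receptacle_light(ctx, TRUE)
      notify(ctx, "reward_available", list())
    })

  handlers <- list(
    active = list(
      poke = function(ctx, time, hole) enter_state(ctx, "reward")),
    reward = list(
      receptacle_in = function(ctx, time, hole) {
        notify(ctx, "reward_collected", list())
      },
      receptacle_out = function(ctx, time, hole) {
        set_receptacle_light(ctx, FALSE)
        enter_state(ctx, "active")
      })
  )

  new_task("habituation", states = c("active", "reward"), initial = "active",
           params = p, param_record = c(reward_ul = p$reward_ul),
           on_start = function(ctx) set_house_light(ctx, TRUE),
           on_enter = on_enter, handlers = handlers,
           cues = c("stimulus_on", "reward_available", "reward_collected"))
}

# ---- 5-CSWM (DMTP) -------------------------------------------------------

#' Build the 5-choice spatial working memory task
#'
#' Delayed matching to position. Sample phase (SP): one hole is lit for at
#' most `sp_sd_ms`; poking it earns the small reward. After the SP reward
#' collection ends (receptacle exit) a delay runs, then the choice phase (CP)
#' presents the sample hole plus one uniformly drawn distractor; poking the
#' sample hole again (match) earns the large reward. Incorrect responses or
#' omissions in either phase abort the trial with a time-out and a subsequent
#' ITI. The house light is off in the default mode and on during time-outs.
#'
#' @param params A [fivecswm_params()] object.
#' @return An `fc_task` machine for [run_session()].
#' @export
build_5cswm <- function(params = fivecswm_params()) {
  stopifnot(inherits(params, "fivecswm_params"))
  p <- params

  lights_off <- function(ctx) {
    for (h in which(ctx$hole_lights)) set_hole_light(ctx, h, FALSE)
  }

  on_enter <- list(
    iti = function(ctx) {
      if (!note_trial_start(ctx)) return(invisible(NULL))
      ctx$deadline <- ctx$now + p$iti_ms
      set_timer(ctx, "iti_end", p$iti_ms)
      notify(ctx, "iti_start", list(iti_ms = p$iti_ms))
    },
    sp_stimulus = function(ctx) {
      set_hole_light(ctx, ctx$sample_hole, TRUE)
      ctx$win_end <- ctx$now + p$sp_sd_ms
      set_timer(ctx, "sp_sd_end", p$sp_sd_ms)
      notify(ctx, "stimulus_on",
             list(target = ctx$sample_hole,
                  alternatives = setdiff(1:5, ctx$sample_hole),
                  window_ms = p$sp_sd_ms))
    },
    sp_reward = function(ctx) {
      dispense_reward(ctx, p$sp_reward_ul)
      set_receptacle_light(ctx, TRUE)
      notify(ctx, "reward_available", list())
    },
    delay = function(ctx) {
      set_timer(ctx, "delay_end", p$delay_ms)
      notify(ctx, "delay_start", list())
    },
    cp_stimulus = function(ctx) {
      if (ctx$distractor_hole == ctx$sample_hole) {
        engine_fault("choice-phase distractor equals the sample hole")
      }
      set_hole_light(ctx, ctx$sample_hole, TRUE)
      set_hole_light(ctx, ctx$distractor_hole, TRUE)
      ctx$win_end <- ctx$now + p$cp_sd_ms
      set_timer(ctx, "cp_sd_end", p$cp_sd_ms)
      notify(ctx, "stimulus_on",
             list(target = ctx$sample_hole,
                  alternatives = ctx$distractor_hole,
                  window_ms = p$cp_sd_ms))
    },
    cp_reward = function(ctx) {
      dispense_reward(ctx, p$cp_reward_ul)
      set_receptacle_light(ctx, TRUE)
      notify(ctx, "reward_available", list())
    },
    timeout = function(ctx) {
      lights_off(ctx)
      set_house_light(ctx, TRUE)   # inverted polarity: light ON in time-out
      set_timer(ctx, "timeout_end", p$timeout_ms)
      notify(ctx, "timeout_start", list())
    })

  handlers <- list(
    iti = list(
      # pokes during the DMTP inter-trial interval are logged, not scored
      iti_end = function(ctx, time, hole) {
        ctx$sample_hole <- with_stream(ctx$rng_task, sample.int(5L, 1L))
        enter_state(ctx, "sp_stimulus")
      }),
    sp_stimulus = list(
      poke = function(ctx, time, hole) {
        if (time >= ctx$win_end) return(invisible(NULL))
        lights_off(ctx)
        if (hole == ctx$sample_hole) enter_state(ctx, "sp_reward")
        else enter_state(ctx, "timeout")                   # SP incorrect
      },
      sp_sd_end = function(ctx, time, hole) {
        lights_off(ctx)
        enter_state(ctx, "timeout")                        # SP omission
      }),
    sp_reward = list(
      receptacle_in = function(ctx, time, hole) {
        notify(ctx, "reward_collected", list())
      },
      receptacle_out = function(ctx, time, hole) {
        set_receptacle_light(ctx, FALSE)
        enter_state(ctx, "delay")                          # collection ended
      }),
    delay = list(
      delay_end = function(ctx, time, hole) {
        others <- setdiff(1:5, ctx$sample_hole)
        ctx$distractor_hole <-
          with_stream(ctx$rng_task, others[sample.int(4L, 1L)])
        enter_state(ctx, "cp_stimulus")
      }),
    cp_stimulus = list(
      poke = function(ctx, time, hole) {
        if (time >= ctx$win_end) return(invisible(NULL))
        lights_off(ctx)
        if (hole == ctx$sample_hole) enter_state(ctx, "cp_reward")  # match
        else enter_state(ctx, "timeout")                   # non-match
      },
      cp_sd_end = function(ctx, time, hole) {
        lights_off(ctx)
        enter_state(ctx, "timeout")                        # CP omission
      }),
    cp_reward = list(
      receptacle_in = function(ctx, time, hole) {
        notify(ctx, "reward_collected", list())
      },
      receptacle_out = function(ctx, time, hole) {
        set_receptacle_light(ctx, FALSE)
        enter_state(ctx, "iti")
      }),
    timeout = list(
      timeout_end = function(ctx, time, hole) {
        set_house_light(ctx, FALSE)
        enter_state(ctx, "iti")
      })
  )

  rec <- c(sp_sd_ms = p$sp_sd_ms, cp_sd_ms = p$cp_sd_ms,
           delay_ms = p$delay_ms, sp_reward_ul = p$sp_reward_ul,
           cp_reward_ul = p$cp_reward_ul, timeout_ms = p$timeout_ms,
           iti_ms = p$iti_ms)
  new_task("5cswm",
           states = c("iti", "sp_stimulus", "sp_reward", "delay",
                      "cp_stimulus", "cp_reward", "timeout"),
           initial = "iti", params = p, param_record = rec,
           on_start = NULL,   # house light off by default in this paradigm
           on_enter = on_enter, handlers = handlers,
           cues = c("iti_start", "stimulus_on", "reward_available",
                    "reward_collected", "delay_start", "timeout_start"))
}

# ---- opto / TTL schedules ------------------------------------------------

#' Attach a TTL pulse schedule to a task
#'
#' Each occurrence of the anchor event emits TTL-high at
#' `anchor + onset_offset_ms` and TTL-low `pulse_ms` later on the given
#' channel, e.g. a pulse covering the first 4 s of every ITI or the first 2 s
#' of every reward collection. Pulse timers persist across task-state
#' changes.
#'
#' @param task An `fc_task` machine.
#' @param schedule An [opto_schedule()].
#' @return The task with the schedule attached.
#' @export
attach_opto_schedule <- function(task, schedule) {
  stopifnot(inherits(task, "fc_task"), inherits(schedule, "opto_schedule"))
  if (!schedule$cue %in% task$cues) {
    config_error(sprintf("task '%s' has no anchor event '%s'",
                         task$paradigm, schedule$anchor))
  }
  task$opto <- c(task$opto, list(schedule))
  ch <- schedule$channel
  hi <- sprintf("opto%d_high", ch)
  lo <- sprintf("opto%d_low", ch)
  task$global_handlers[[hi]] <- function(ctx, time, hole) {
    set_ttl(ctx, ch, TRUE)
  }
  task$global_handlers[[lo]] <- function(ctx, time, hole) {
    set_ttl(ctx, ch, FALSE)
  }
  task$persistent_timers <- unique(c(task$persistent_timers, hi, lo))
  task
}
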