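# Virtual subjects. A stochastic agent with interpretable behavioural rates
# drives large simulations; a scripted agent replays an exact action list for
# hand-checkable traces. Agents react to task cues (stimulus on, ITI start,
# reward available, time-out) and plan timed inputs; a new cue replaces the
# stochastic agent's pending plan.

#' Behavioural parameters of the stochastic virtual subject
#'
#' @param p_respond Probability of responding at all on a cued presentation.
#' @param p_correct Probability that a response goes to the cued hole;
#'   otherwise the hole is drawn uniformly from the presented alternatives
#'   (the four other holes in the 5-CSRTT; the distractor in the 5-CSWM
#'   choice phase). `p_correct = 0.2` in the 5-CSRTT therefore yields a
#'   uniform choice over all five holes, i.e. chance-level responding.
#' @param premature_hazard Rate (events/s) of premature pokes during the ITI;
#'   the first premature time is exponential, so the premature fraction over
#'   many trials of ITI `T` seconds is `1 - exp(-hazard * T)`.
#' @param resp_meanlog,resp_sdlog Log-normal response-latency parameters (ms);
#'   draws are resampled into the legal response window so `p_respond` keeps
#'   its meaning.
#' @param rew_meanlog,rew_sdlog Log-normal reward (magazine) latency
#'   parameters (ms): time from reward availability to receptacle entry.
#' @param dwell_ms Time spent in the receptacle consuming the reward; the
#'   next ITI starts at receptacle exit.
#' @return An `agent_params` object.
#' @export
agent_params <- function(p_respond = 0.8, p_correct = 0.8,
                         premature_hazard = 0.05,
                         resp_meanlog = log(600), resp_sdlog = 0.4,
                         rew_meanlog = log(800), rew_sdlog = 0.35,
                         dwell_ms = 1500) {
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      config_error(sprintf("`%s` must be a probability in [0, 1]", name))
    }
    as.numeric(x)
  }
  if (!is.numeric(premature_hazard) || premature_hazard < 0) {
    config_error("`premature_hazard` must be >= 0 (events/s)")
  }
  structure(list(p_respond = chk_prob(p_respond, "p_respond"),
                 p_correct = chk_prob(p_correct, "p_correct"),
                 premature_hazard = as.numeric(premature_hazard),
                 resp_meanlog = resp_meanlog, resp_sdlog = resp_sdlog,
                 rew_meanlog = rew_meanlog, rew_sdlog = rew_sdlog,
                 dwell_ms = check_pos(dwell_ms, "dwell_ms")),
            class = "agent_params")
}

# latency resampled (not censored) into [1, window) ms
sample_response_latency <- function(meanlog, sdlog, window_ms) {
  for (i in 1:100) {
    lat <- round(stats::rlnorm(1L, meanlog, sdlog))
    if (lat >= 1 && (is.infinite(window_ms) || lat < window_ms)) return(lat)
  }
  max(1, floor(stats::runif(1L, 1, window_ms)))  # degenerate parameters
}

#' Stochastic virtual subject
#'
#' @param params An [agent_params()] object.
#' @return An `fc_agent` for [run_session()].
#' @examples
#' # chance-level responder: responds on every trial, uniformly over 5 holes
#' chance <- stochastic_agent(agent_params(p_respond = 1, p_correct = 0.2,
#'                                         premature_hazard = 0))
#' @export
stochastic_agent <- function(params = agent_params()) {
  stopifnot(inherits(params, "agent_params"))
  p <- params
  handle <- function(mem, cue, data, now) {
    switch(cue,
      iti_start = {
        acts <- NULL
        if (p$premature_hazard > 0) {
          dt <- stats::rexp(1L, rate = p$premature_hazard) * 1000
          hole <- sample.int(5L, 1L)
          acts <- data.frame(time = now + max(1, round(dt)),
                             action = "poke", hole = hole)
        }
        list(actions = acts, cancel = TRUE)
      },
      stimulus_on = {
        if (stats::runif(1L) > p$p_respond) return(list(cancel = TRUE))
        lat <- sample_response_latency(p$resp_meanlog, p$resp_sdlog,
                                       data$window_ms)
        target <- data$target
        alts <- data$alternatives
        hole <- if (!is.na(target) && stats::runif(1L) <= p$p_correct) {
          target
        } else {
          alts[sample.int(length(alts), 1L)]
        }
        list(actions = data.frame(time = now + lat, action = "poke",
                                  hole = hole),
             cancel = TRUE)
      },
      reward_available = {
        t_in <- now + max(1, round(stats::rlnorm(1L, p$rew_meanlog,
                                                 p$rew_sdlog)))
        t_out <- t_in + round(p$dwell_ms)
        list(actions = data.frame(time = c(t_in, t_out),
                                  action = c("receptacle_in",
                                             "receptacle_out"),
                                  hole = NA_integer_),
             cancel = TRUE)
      },
      timeout_start = list(cancel = TRUE),
      NULL)
  }
  structure(list(kind = "stochastic", params = p, init = NULL,
                 handle = handle),
            class = "fc_agent")
}

#' Scripted virtual subject
#'
#' Replays a fixed action list verbatim, regardless of task state. Useful for
#' exact, hand-checkable traces: the engine logs every input whether or not
#' the task acts on it.
#'
#' @param script Data frame with columns `time_ms` (strictly increasing
#'   integer ms), `action` (`"poke"`, `"receptacle_in"`, `"receptacle_out"`)
#'   and `hole` (1-5 for pokes, NA otherwise).
#' @return An `fc_agent` for [run_session()].
#' @examples
#' # one correct poke, then reward collection
#' script <- data.frame(time_ms = c(5800, 7000, 9000),
#'                      action = c("poke", "receptacle_in", "receptacle_out"),
#'                      hole = c(3L, NA, NA))
#' @export
scripted_agent <- function(script) {
  script <- validate_script(script)
  init <- function(ctx) {
    for (i in seq_len(nrow(script))) {
      queue_push(ctx, script$time_ms[i], EVENT_CLASS_INPUT,
                 script$action[i], hole = script$hole[i], agent = FALSE)
    }
  }
  structure(list(kind = "scripted", script = script, init = init,
                 handle = NULL),
            class = "fc_agent")
}

validate_script <- function(script) {
  stopifnot(is.data.frame(script))
  need <- c("time_ms", "action")
  if (!all(need %in% names(script))) {
    config_error("script needs columns time_ms, action (and optionally hole)")
  }
  if (!"hole" %in% names(script)) script$hole <- NA_integer_
  if (nrow(script) && any(diff(script$time_ms) <= 0)) {
    config_error("script times must be strictly increasing")
  }
  ok <- script$action %in% c("poke", "receptacle_in", "receptacle_out")
  if (!all(ok)) {
    config_error(sprintf("unknown script action '%s'",
                         script$action[which(!ok)[1L]]))
  }
  if (any(script$action == "poke" &
          (is.na(script$hole) | script$hole < 1 | script$hole > 5))) {
    config_error("poke actions need a hole index in 1..5")
  }
  script$time_ms <- as.integer(script$time_ms)
  script$hole <- as.integer(script$hole)
  script
}

#' Read an agent script from CSV
#'
#' Expects columns `time_ms, action, hole` as documented in
#' [scripted_agent()].
#'
#' @param path CSV file path.
#' @return A validated script data frame.
#' @export
read_script_csv <- function(path) {
  validate_script(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.fc_agent <- function(x, ...) {
  cat(sprintf("<fc_agent: %s>\n", x$kind))
  if (x$kind == "stochastic") {
    p <- x$params
    cat(sprintf("  p_respond=%.3g p_correct=%.3g premature_hazard=%.3g/s\n",
                p$p_respond, p$p_correct, p$premature_hazard))
  } else {
    cat(sprintf("  %d scripted actions\n", nrow(x$script)))
  }
  invisible(x)
}
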