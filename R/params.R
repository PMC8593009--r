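# Task parameter objects. Baseline values are the printed task defaults:
# 5-CSRTT baseline SD 2 s, ITI 5 s, LH 2 s, 5 s time-out, 20 ul reward;
# habituation 40 ul; 5-CSWM sample-phase max SD 10 s, choice-phase max SD 5 s,
# 2 s post-collection delay, 10/60 ul rewards.

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    config_error(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

#' 5-CSRTT task parameters
#'
#' @param sd_ms Stimulus duration (ms): how long the cue hole stays lit.
#' @param iti_ms Inter-trial interval (ms) preceding each stimulus; pokes
#'   during it are premature responses.
#' @param lh_ms Limited hold (ms): post-stimulus window in which a poke still
#'   counts.
#' @param timeout_ms Time-out (ms) after premature/incorrect/omission trials,
#'   signalled by house light off.
#' @param reward_ul Reward volume (microlitres) for a correct response.
#' @param iti_set Optional numeric vector of ITIs; when given, each trial's
#'   ITI is drawn uniformly (seeded) from this set (variable-ITI challenge).
#' @return A `fivecsrtt_params` object.
#' @examples
#' fivecsrtt_params()                      # baseline stage
#' fivecsrtt_params(sd_ms = 800)           # attention challenge
#' @export
fivecsrtt_params <- function(sd_ms = 2000, iti_ms = 5000, lh_ms = 2000,
                             timeout_ms = 5000, reward_ul = 20,
                             iti_set = NULL) {
  p <- list(sd_ms = check_pos(sd_ms, "sd_ms"),
            iti_ms = check_pos(iti_ms, "iti_ms"),
            lh_ms = check_pos(lh_ms, "lh_ms"),
            timeout_ms = check_pos(timeout_ms, "timeout_ms"),
            reward_ul = check_pos(reward_ul, "reward_ul"),
            iti_set = iti_set)
  if (!is.null(iti_set)) {
    if (!is.numeric(iti_set) || length(iti_set) < 1L || any(iti_set <= 0)) {
      config_error("`iti_set` must be a vector of positive ITIs (ms)")
    }
    p$iti_set <- as.numeric(iti_set)
  }
  structure(p, class = "fivecsrtt_params")
}

#' Habituation-training parameters
#'
#' All five holes are illuminated for an unlimited time; any 5-choice poke
#' earns the reward at the illuminated receptacle.
#'
#' @param reward_ul Reward volume (microlitres) per poke.
#' @return A `habituation_params` object.
#' @export
habituation_params <- function(reward_ul = 40) {
  structure(list(reward_ul = check_pos(reward_ul, "reward_ul")),
            class = "habituation_params")
}

#' 5-CSWM (delayed-matching-to-position) task parameters
#'
#' Each trial is sample phase (SP: one lit hole, small reward), a delay after
#' the SP reward collection ends, then choice phase (CP: the sample hole plus
#' one distractor lit; matching poke earns the large reward). House-light
#' polarity is inverted relative to the 5-CSRTT: off during the task, on
#' during time-outs.
#'
#' @param sp_sd_ms Maximum sample-phase stimulus duration (ms).
#' @param cp_sd_ms Maximum choice-phase stimulus duration (ms).
#' @param delay_ms Delay (ms) between SP reward-collection end and CP onset.
#' @param sp_reward_ul,cp_reward_ul Reward volumes (microlitres) for the SP
#'   poke and the CP matching poke.
#' @param timeout_ms Time-out (ms) after incorrect responses or omissions.
#' @param iti_ms Inter-trial interval (ms).
#' @return A `fivecswm_params` object.
#' @export
fivecswm_params <- function(sp_sd_ms = 10000, cp_sd_ms = 5000,
                            delay_ms = 2000, sp_reward_ul = 10,
                            cp_reward_ul = 60, timeout_ms = 5000,
                            iti_ms = 5000) {
  structure(list(sp_sd_ms = check_pos(sp_sd_ms, "sp_sd_ms"),
                 cp_sd_ms = check_pos(cp_sd_ms, "cp_sd_ms"),
                 delay_ms = check_pos(delay_ms, "delay_ms"),
                 sp_reward_ul = check_pos(sp_reward_ul, "sp_reward_ul"),
                 cp_reward_ul = check_pos(cp_reward_ul, "cp_reward_ul"),
                 timeout_ms = check_pos(timeout_ms, "timeout_ms"),
                 iti_ms = check_pos(iti_ms, "iti_ms")),
            class = "fivecswm_params")
}

#' Derive a challenge protocol from baseline 5-CSRTT parameters
#'
#' Challenge protocols stress a specific function while leaving everything
#' else at baseline: the attention challenge shortens the stimulus duration
#' (default from 2 s to 0.8 s); ITI challenges lengthen or randomize the
#' waiting period to load on impulse control.
#'
#' @param base A [fivecsrtt_params()] object.
#' @param kind `"attention"` (set SD to `magnitude`, default 800 ms),
#'   `"fixed_iti"` (set ITI to `magnitude`), or `"variable_iti"` (draw each
#'   trial's ITI from the set `magnitude`, default `c(5000, 7500, 12500)` ms —
#'   a configurable placeholder set).
#' @param magnitude Challenge magnitude; see `kind`.
#' @return A modified `fivecsrtt_params` object.
#' @examples
#' make_challenge(fivecsrtt_params(), "attention")  # SD 800 ms, ITI unchanged
#' @export
make_challenge <- function(base, kind = c("attention", "fixed_iti",
                                          "variable_iti"),
                           magnitude = NULL) {
  stopifnot(inherits(base, "fivecsrtt_params"))
  kind <- match.arg(kind)
  switch(kind,
    attention = {
      sd <- if (is.null(magnitude)) 800 else magnitude
      fivecsrtt_params(sd_ms = sd, iti_ms = base$iti_ms, lh_ms = base$lh_ms,
                       timeout_ms = base$timeout_ms,
                       reward_ul = base$reward_ul, iti_set = base$iti_set)
    },
    fixed_iti = {
      if (is.null(magnitude)) config_error("fixed_iti challenge needs `magnitude` (ms)")
      fivecsrtt_params(sd_ms = base$sd_ms, iti_ms = magnitude,
                       lh_ms = base$lh_ms, timeout_ms = base$timeout_ms,
                       reward_ul = base$reward_ul)
    },
    variable_iti = {
      set <- if (is.null(magnitude)) c(5000, 7500, 12500) else magnitude
      fivecsrtt_params(sd_ms = base$sd_ms, iti_ms = base$iti_ms,
                       lh_ms = base$lh_ms, timeout_ms = base$timeout_ms,
                       reward_ul = base$reward_ul, iti_set = set)
    })
}

#' Optogenetic/TTL pulse schedule
#'
#' Anchors a TTL pulse to a recurring task event, e.g. a pulse covering the
#' first 4 s of every ITI, or the first 2 s of every reward collection.
#'
#' @param anchor `"iti_onset"` or `"reward_collection"` (receptacle entry
#'   after a correct response).
#' @param pulse_ms Pulse duration (ms).
#' @param channel TTL output channel (1-4).
#' @param onset_offset_ms Delay (ms) from the anchor to TTL-high.
#' @return An `opto_schedule` object.
#' @seealso [attach_opto_schedule()]
#' @export
opto_schedule <- function(anchor = c("iti_onset", "reward_collection"),
                          pulse_ms, channel = 1L, onset_offset_ms = 0) {
  anchor <- match.arg(anchor)
  pulse_ms <- check_pos(pulse_ms, "pulse_ms")
  if (!is.numeric(onset_offset_ms) || onset_offset_ms < 0) {
    config_error("`onset_offset_ms` must be >= 0")
  }
  if (!is.numeric(channel) || length(channel) != 1L || channel < 1 ||
      channel > 4) {
    config_error("`channel` must be a TTL channel index in 1..4")
  }
  structure(list(anchor = anchor,
                 cue = switch(anchor, iti_onset = "iti_start",
                              reward_collection = "reward_collected"),
                 pulse_ms = pulse_ms,
                 channel = as.integer(channel),
                 onset_offset_ms = as.numeric(onset_offset_ms)),
            class = "opto_schedule")
}
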