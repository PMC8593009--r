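# Shared fixture builders. Scripted sessions are the hand-checkable oracles:
# given the documented seeding policy (the task stream is seeded with
# set.seed(seed) and draws one sample.int() per stimulus), the cued-hole
# sequence can be derived independently of the engine, and every event time
# of a scripted trial can be computed by hand from the task parameters.

# cued holes the 5-CSRTT task stream will draw for a given seed
expected_cued_holes <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i) sample.int(5L, 1L), integer(1))
}

# sample hole and distractor the 5-CSWM task stream will draw for one trial
expected_cswm_holes <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample_hole <- sample.int(5L, 1L)
  others <- setdiff(1:5, sample_hole)
  distractor <- others[sample.int(4L, 1L)]
  c(sample = sample_hole, distractor = distractor)
}

make_script <- function(times, actions, holes = NA_integer_) {
  data.frame(time_ms = times, action = actions,
             hole = rep_len(holes, length(times)))
}

run_scripted_5csrtt <- function(script, seed = 1, duration_ms = 30000,
                                params = fivecsrtt_params()) {
  run_session(build_5csrtt(params), scripted_agent(script),
              seed = seed, duration_ms = duration_ms)
}

perfect_params <- function() {
  agent_params(p_respond = 1, p_correct = 1, premature_hazard = 0)
}

event_times <- function(log, event, payload = NULL) {
  rows <- log$event == event
  if (!is.null(payload)) rows <- rows & log$payload == payload
  log$time_ms[rows]
}
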