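# Paradigm rules: reward volumes, time-out brackets, response windows,
# house-light polarity, challenge protocols, opto schedules.

test_that("a correct 5-CSRTT response earns the 20 ul reward", {
  cued <- expected_cued_holes(1, 1)
  script <- make_script(c(5800, 7000, 9000),
                        c("poke", "receptacle_in", "receptacle_out"),
                        c(cued, NA, NA))
  log <- run_scripted_5csrtt(script, seed = 1, duration_ms = 10000)
  rew <- strsplit(log$payload[log$event == "reward"], ";")[[1]]
  expect_equal(as.numeric(rew[1]), 20)
  tr <- trials_5csrtt(log)
  expect_equal(tr$class, "correct")
  expect_equal(tr$response_latency_ms, 800)
  expect_equal(tr$reward_latency_ms, 1200)
})

test_that("an incorrect poke triggers an exact 5 s house-light-off time-out", {
  cued <- expected_cued_holes(1, 1)
  wrong <- (cued %% 5) + 1
  script <- make_script(5800, "poke", wrong)
  log <- run_scripted_5csrtt(script, seed = 1, duration_ms = 12000)
  off <- event_times(log, "house_light_off")[1]
  on <- event_times(log, "house_light_on")
  on_after <- on[on > off][1]
  expect_equal(off, 5800)
  expect_equal(on_after - off, 5000)
  expect_equal(trials_5csrtt(log)$class[1], "incorrect")
})

test_that("a poke during the ITI is premature and aborts the trial", {
  script <- make_script(1000, "poke", 4)
  log <- run_scripted_5csrtt(script, seed = 1, duration_ms = 7000)
  tr <- trials_5csrtt(log)
  expect_equal(tr$class[1], "premature")
  # no stimulus was presented in that trial
  expect_false(any(log$event == "hole_light_on" & log$time_ms < 6000))
  # time-out starts at the poke
  expect_equal(event_times(log, "state", "timeout")[1], 1000)
})

test_that("the limited-hold boundary is half-open", {
  cued <- expected_cued_holes(1, 1)
  # stimulus 5000-7000, limited hold to 9000
  hit <- run_scripted_5csrtt(make_script(8999, "poke", cued),
                             seed = 1, duration_ms = 11000)
  expect_equal(trials_5csrtt(hit)$class[1], "correct")
  miss <- run_scripted_5csrtt(make_script(9000, "poke", cued),
                              seed = 1, duration_ms = 15000)
  expect_equal(trials_5csrtt(miss)$class[1], "omission")
  # poke at exactly stimulus end still counts (it falls in the limited hold)
  at_sd <- run_scripted_5csrtt(make_script(7000, "poke", cued),
                               seed = 1, duration_ms = 11000)
  expect_equal(trials_5csrtt(at_sd)$class[1], "correct")
})

test_that("an unanswered trial is an omission after SD + LH", {
  log <- run_scripted_5csrtt(make_script(numeric(0), character(0)),
                             seed = 1, duration_ms = 14000)
  tr <- trials_5csrtt(log)
  expect_equal(tr$class[1], "omission")
  # light off at SD end; time-out entry LH later
  expect_equal(event_times(log, "hole_light_off")[1], 7000)
  expect_equal(event_times(log, "state", "timeout")[1], 9000)
})

test_that("habituation rewards every poke with 40 ul from lit holes", {
  script <- make_script(c(1000, 2000, 3000, 4000, 5000, 6000,
                          7000, 8000, 9000),
                        rep(c("poke", "receptacle_in", "receptacle_out"), 3),
                        c(2, NA, NA, 5, NA, NA, 1, NA, NA))
  log <- run_session(build_habituation(), scripted_agent(script),
                     seed = 1, duration_ms = 10000)
  s <- summarize_habituation(log)
  expect_equal(s$n_rewards, 3)
  expect_equal(s$total_reward_ul, 120)
  rew <- vapply(strsplit(log$payload[log$event == "reward"], ";"),
                function(x) as.numeric(x[1]), numeric(1))
  expect_equal(rew, c(40, 40, 40))
  # all five holes lit at session start, never extinguished mid-session
  expect_equal(sort(as.integer(log$payload[log$event == "hole_light_on" &
                                             log$time_ms == 0])), 1:5)
})

test_that("an empty habituation session earns nothing and ends on time", {
  log <- run_session(build_habituation(),
                     scripted_agent(make_script(numeric(0), character(0))),
                     seed = 1, duration_ms = 8000)
  s <- summarize_habituation(log)
  expect_equal(s$n_rewards, 0)
  expect_equal(log$time_ms[log$event == "session_end"], 8000)
})

test_that("5-CSWM pays 10 ul in the sample and 60 ul in the choice phase", {
  h <- expected_cswm_holes(3)
  # iti 5000 | SP at 5000, poke 5600 | collect 6600-8600 | delay to 10600 |
  # CP at 10600, poke 11100 | collect 12100-13100
  script <- make_script(c(5600, 6600, 8600, 11100, 12100, 13100),
                        c("poke", "receptacle_in", "receptacle_out",
                          "poke", "receptacle_in", "receptacle_out"),
                        c(h["sample"], NA, NA, h["sample"], NA, NA))
  log <- run_session(build_5cswm(), scripted_agent(script),
                     seed = 3, duration_ms = 14000)
  rew <- vapply(strsplit(log$payload[log$event == "reward"], ";"),
                function(x) as.numeric(x[1]), numeric(1))
  expect_equal(rew, c(10, 60))
  # delay between SP-collection end and CP onset is exactly 2 s
  expect_equal(event_times(log, "state", "delay"), 8600)
  expect_equal(event_times(log, "state", "cp_stimulus"), 10600)
  # CP presents exactly two lit holes: the sample plus one distractor
  cp_lights <- log$payload[log$event == "hole_light_on" &
                             log$time_ms == 10600]
  expect_equal(sort(as.integer(cp_lights)),
               sort(unname(h)))
  tr <- trials_5cswm(log)
  expect_equal(tr$sp_class, "correct")
  expect_equal(tr$cp_class, "match")
  expect_equal(tr$sp_response_latency_ms, 600)
})

test_that("a sample-phase omission aborts the trial: no choice phase occurs", {
  log <- run_session(build_5cswm(),
                     scripted_agent(make_script(numeric(0), character(0))),
                     seed = 3, duration_ms = 25000)
  tr <- trials_5cswm(log)
  expect_equal(tr$sp_class[1], "omission")
  expect_true(is.na(tr$cp_class[1]))
  expect_false(any(log$event == "state" & log$payload == "cp_stimulus" &
                     log$time_ms <= 20000))
})

test_that("house-light polarity is inverted between the two paradigms", {
  # 5-CSRTT: light on except during time-outs
  log_a <- run_scripted_5csrtt(make_script(1000, "poke", 1),
                               seed = 1, duration_ms = 7000)
  expect_equal(log_a$time_ms[log_a$event == "house_light_on"][1], 0)
  expect_equal(log_a$time_ms[log_a$event == "house_light_off"][1], 1000)
  # 5-CSWM: light off by default, on during time-outs
  h <- expected_cswm_holes(3)
  wrong <- setdiff(1:5, h["sample"])[1]
  log_b <- run_session(build_5cswm(),
                       scripted_agent(make_script(5600, "poke", wrong)),
                       seed = 3, duration_ms = 11000)
  expect_false(any(log_b$event == "house_light_on" & log_b$time_ms < 5600))
  expect_equal(log_b$time_ms[log_b$event == "house_light_on"][1], 5600)
  to_on <- log_b$time_ms[log_b$event == "house_light_on"][1]
  to_off <- log_b$time_ms[log_b$event == "house_light_off"]
  expect_equal(to_off[to_off > to_on][1] - to_on, 5000)
  expect_equal(trials_5cswm(log_b)$sp_class[1], "incorrect")
})

test_that("5-CSWM never reaches a choice phase without a sample-phase correct", {
  log <- run_session(build_5cswm(),
                     stochastic_agent(agent_params(p_respond = 0.6,
                                                   p_correct = 0.6,
                                                   premature_hazard = 0)),
                     seed = 5, duration_ms = 600000)
  tr <- trials_5cswm(log)
  expect_gt(nrow(tr), 10)
  expect_true(all(is.na(tr$cp_class[tr$sp_class != "correct"])))
  expect_true(all(!is.na(tr$cp_class[tr$sp_class == "correct"])))
  expect_true(all(tr$distractor_hole[!is.na(tr$cp_class)] !=
                    tr$sample_hole[!is.na(tr$cp_class)], na.rm = TRUE))
})

test_that("challenge constructors modify exactly the advertised parameter", {
  base <- fivecsrtt_params()
  att <- make_challenge(base, "attention")
  expect_equal(att$sd_ms, 800)
  expect_equal(att$iti_ms, 5000)
  expect_equal(att$lh_ms, base$lh_ms)
  fix <- make_challenge(base, "fixed_iti", 9000)
  expect_equal(fix$iti_ms, 9000)
  expect_equal(fix$sd_ms, 2000)
  var <- make_challenge(base, "variable_iti")
  expect_equal(var$iti_set, c(5000, 7500, 12500))
  expect_error(make_challenge(base, "sideways"), "arg")
})

test_that("variable-ITI draws are reproducible and roughly uniform", {
  params <- make_challenge(fivecsrtt_params(), "variable_iti")
  empty <- scripted_agent(make_script(numeric(0), character(0)))
  observed_itis <- function(seed) {
    log <- run_session(build_5csrtt(params), empty, seed = seed,
                       duration_ms = 1200000)
    iti_t <- event_times(log, "state", "iti")
    stim_t <- event_times(log, "state", "stimulus")
    stim_t - iti_t[seq_along(stim_t)]
  }
  a <- observed_itis(9)
  b <- observed_itis(9)
  expect_identical(a, b)
  expect_true(all(a %in% c(5000, 7500, 12500)))
  expect_gt(length(a), 50)
  ht <- suppressWarnings(stats::chisq.test(table(factor(
    a, levels = c(5000, 7500, 12500)))))
  expect_gt(ht$p.value, 0.001)
})

test_that("opto schedules bracket their anchors and empty schedules stay silent", {
  # ITI anchor: TTL high at every ITI onset, low 4 s later
  task <- attach_opto_schedule(build_5csrtt(),
                               opto_schedule("iti_onset", pulse_ms = 4000,
                                             channel = 1))
  log <- run_session(task, scripted_agent(make_script(numeric(0),
                                                      character(0))),
                     seed = 1, duration_ms = 30000)
  iti_t <- event_times(log, "state", "iti")
  hi <- event_times(log, "ttl_high")
  lo <- event_times(log, "ttl_low")
  expect_equal(hi, iti_t)
  # pulses that fit in the session last exactly 4 s; a final pulse running
  # into session end is closed early by the device shutdown
  fits <- hi + 4000 <= 30000
  expect_equal(lo[fits] - hi[fits], rep(4000, sum(fits)))

  # reward-collection anchor: bracket at receptacle entry after a correct
  cued <- expected_cued_holes(1, 1)
  task2 <- attach_opto_schedule(build_5csrtt(),
                                opto_schedule("reward_collection",
                                              pulse_ms = 2000, channel = 3))
  log2 <- run_session(task2, scripted_agent(make_script(
    c(5800, 7000, 9500), c("poke", "receptacle_in", "receptacle_out"),
    c(cued, NA, NA))), seed = 1, duration_ms = 10000)
  expect_equal(event_times(log2, "ttl_high"), 7000)
  expect_equal(event_times(log2, "ttl_low"), 9000)

  # no schedule -> no TTL events at all
  log3 <- run_scripted_5csrtt(make_script(numeric(0), character(0)),
                              seed = 1, duration_ms = 30000)
  expect_false(any(log3$event %in% c("ttl_high", "ttl_low")))

  expect_error(opto_schedule("iti_onset", pulse_ms = 4000, channel = 9),
               "channel")
})

test_that("response classes partition the classified trials", {
  for (seed in 1:3) {
    log <- run_session(build_5csrtt(),
                       stochastic_agent(agent_params(p_respond = 0.7,
                                                     p_correct = 0.6,
                                                     premature_hazard = 0.08)),
                       seed = seed, duration_ms = 600000)
    tr <- trials_5csrtt(log)
    expect_true(all(tr$class %in% c("correct", "incorrect", "premature",
                                    "omission")))
    m <- compute_5csrtt_metrics(tr)
    expect_equal(m$n_correct + m$n_incorrect + m$n_premature + m$n_omission,
                 m$n_trials)
    # reward conservation: dispensed volume matches correct count * 20 ul
    vols <- vapply(strsplit(log$payload[log$event == "reward"], ";"),
                   function(x) as.numeric(x[1]), numeric(1))
    expect_equal(sum(vols), 20 * m$n_correct)
  }
})
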