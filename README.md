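# fivechoice

Discrete-event simulation and analysis of 5-choice operant behaviour in R.

Operant boxes with a five-hole nose-poke wall are a workhorse of rodent
cognitive neuroscience: brief light cues in one of five holes probe sustained
attention (5-choice serial reaction time task, 5-CSRTT), and a
delayed-matching-to-position variant probes spatial working memory (5-CSWM).
`fivechoice` re-creates such a system entirely in software for people who
develop, validate or teach the *analysis* side of these experiments: task
engines with millisecond event logging, virtual subjects with interpretable
behavioural parameters, the standard performance metrics, criterion-based
training-stage scheduling, and TTL-based alignment of behavioural timestamps
with an electrophysiology acquisition clock.

## The tasks and metrics

A 5-CSRTT trial is an inter-trial interval (ITI, baseline 5 s), a light cue
in one pseudo-random hole for the stimulus duration (SD, baseline 2 s), and a
limited hold (LH, 2 s) after light-off. The four response classes are:

* **correct** — cued hole poked during SD or LH; 20 µl milk at the lit
  receptacle,
* **incorrect** — a non-cued hole poked in that window,
* **premature** — any 5-choice poke during the ITI,
* **omission** — no poke at all,

with every non-correct outcome triggering a 5 s time-out signalled by the
house light switching off. Session metrics follow the standard definitions:

    accuracy   = 100 · correct / (correct + incorrect)
    %omissions = 100 · omissions / trials
    %premature = 100 · prematures / trials

With five holes, chance-level accuracy is 20 %. The 5-CSWM task runs a sample
phase (one lit hole, 10 µl reward), a 2 s delay after reward collection, and
a choice phase (sample hole + one distractor; matching poke earns 60 µl),
with inverted house-light polarity. Habituation rewards any poke with 40 µl
while all five holes stay lit.

## Worked example

```r
library(fivechoice)

task  <- build_5csrtt(fivecsrtt_params())        # 2 s SD, 5 s ITI baseline
agent <- stochastic_agent(agent_params(p_respond = 0.8, p_correct = 0.8,
                                       premature_hazard = 0.05))
log   <- run_session(task, agent, seed = 42)     # one 30-min session

summary <- compute_5csrtt_metrics(trials_5csrtt(log),
                                  duration_ms = attr(log, "duration_ms"))
summary[, c("n_trials", "n_correct", "accuracy",
            "pct_omissions", "pct_premature")]
#>   n_trials n_correct accuracy pct_omissions pct_premature
#> 1      192        87 76.99115      19.27083        21.875
```

The virtual subject responded on 80 % of cued trials, chose the cued hole
with probability 0.8 and emitted premature pokes at 0.05/s during the ITI;
the session of 192 trials measures accuracy 77.0 %, omissions 19.3 % and
premature responding 21.9 %, each recomputed from the millisecond event log
(`log` is a plain data frame of `time_ms, event, payload` rows that
round-trips through `write_event_csv()`/`read_event_csv()`).

Challenge protocols derive from the baseline, e.g. the attention challenge
shortens the SD to 0.8 s:

```r
build_5csrtt(make_challenge(fivecsrtt_params(), "attention"))
```

A shell entry point wraps the same functions
(`inst/cli/fivechoice run|analyze|cohort|align|schedule`); see
`inst/extdata/example_run.yaml` for a session config.

## Package tour

| Area | Functions |
| --- | --- |
| Engine | `run_session`, `dispatch_event`, `volume_to_steps`, `pump_calibration` |
| Tasks | `build_5csrtt`, `build_habituation`, `build_5cswm`, `make_challenge`, `attach_opto_schedule` |
| Subjects | `stochastic_agent`, `scripted_agent`, `agent_params` |
| Logs | `write_event_csv`, `read_event_csv`, `segment_trials`, `classify_5csrtt_trial`, `trials_5csrtt`, `trials_5cswm` |
| Metrics | `compute_5csrtt_metrics`, `compute_5cswm_metrics`, `time_binned_metrics`, `response_share_test`, `latency_summary` |
| Training | `stage_criteria`, `evaluate_transition`, `run_training_simulation`, `default_training_schedule` |
| Clock sync | `fit_clock_mapping`, `map_timestamps`, `simulate_acquisition_clock`, `pulse_train` |

The methods vignette (`vignettes/fivechoice-methods.Rmd`) documents the task
models, the virtual-subject assumptions, numerical choices and known
limitations.
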