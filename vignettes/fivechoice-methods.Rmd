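---
title: "Simulating 5-choice operant behaviour: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating 5-choice operant behaviour: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivechoice)
```

`fivechoice` is a software-only operant-box system: everything a five-hole
nose-poke box does — state-machine task control, millisecond event logging,
reward pumping, TTL signalling — is reproduced as a deterministic
discrete-event simulation driven by virtual subjects. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## The discrete-event engine

Time is an integer count of milliseconds from session start; there is no
wall-clock dependence. All pending work lives in one event queue holding
subject inputs (pokes, receptacle entries and exits) and named timers.
Determinism is a design requirement, not an accident, and rests on three
rules:

1. events are processed in timestamp order;
2. at equal timestamps, subject inputs precede timer expiries; simultaneous
   inputs keep their insertion order and simultaneous timers fire
   alphabetically by name;
3. all randomness flows through two seeded streams derived from the session
   seed — one for task randomness (cued-hole and distractor selection,
   variable-ITI draws), one for the virtual subject — so task and behaviour
   are separately reproducible.

With these rules a session is a pure function of (task, agent, seed,
duration): running it twice yields byte-identical event logs, which the test
suite asserts by file hash.

Timers are cancelled on every state exit unless declared persistent (the
session-end timer and TTL pulse timers, which must straddle state changes).
Every light or TTL line that is on when the session ends is switched off and
logged before the `session_end` event, so on/off events always balance.

### Response windows and boundary cases

All response windows are half-open, `[start, end)`. A poke at exactly the
moment the stimulus light goes out still falls inside the limited hold; a
poke at exactly the end of the limited hold is logged but no longer scored,
and the trial becomes an omission. Because the queue processes inputs before
timers at equal timestamps, the window ends are enforced by an explicit
deadline check in the poke handlers rather than by event ordering — the two
rules would otherwise conflict in the final millisecond of the limited hold.
A poke landing at exactly the ITI end is likewise logged but not scored as
premature: the stimulus it could not yet have seen comes on in the same
millisecond.

### The virtual pump

Reward volumes are coded as stepper-motor steps,
`steps = round(volume / µl_per_step)`, so the delivered volume differs from
the command by at most half a step. The default calibration of 0.5 µl/step
is an explicit placeholder — real pumps are calibrated empirically — and
every reward event logs both the commanded microlitres and the step count.

## The task models

**5-CSRTT.** The operant cycle is: ITI (started at session start, at
receptacle exit after reward collection, or at time-out end) → one hole lit
for the stimulus duration → limited hold after light-off → classification.
Baseline parameters are SD 2 s, ITI 5 s, LH 2 s, time-out 5 s, reward 20 µl,
house light on except during time-outs. A correct poke extinguishes the
stimulus immediately and delivers the reward at once; the immediate-feedback
reading is deliberate, matching the description of reward delivery as
immediate rather than deferred to the scheduled light-off. Premature,
incorrect and omission outcomes each abort the trial instantly into the
time-out, including the upcoming stimulus after a premature poke.

The trial denominator for the percentage metrics is the number of initiated
ITIs whose trial reached any classification — prematures count as trials, as
the premature-rate formula requires. Pokes during time-outs and repeated
pokes after classification (perseverative responses) are logged, because the
log must record every event, but have no task consequence and are not
scored: no standard perseveration score is defined here.

**Challenges** derive from the baseline: the attention challenge sets the SD
to 0.8 s and changes nothing else; fixed-ITI sets a longer ITI; variable-ITI
draws each trial's ITI uniformly (from the task stream) out of a configured
set, default `{5000, 7500, 12500}` ms. That default set is a placeholder
chosen to bracket the baseline ITI the way impulsivity challenges usually
do; it is plainly configurable.

**Habituation.** All five holes lit indefinitely; any poke earns 40 µl at
the lit receptacle and the cycle re-arms at receptacle exit.

**5-CSWM (delayed matching to position).** Sample phase: one lit hole, up to
10 s, 10 µl on a correct poke. The delay (2 s) starts when the reward
collection ends, i.e. at receptacle exit. Choice phase: the sample hole plus
one distractor drawn uniformly from the other four holes, up to 5 s; poking
the sample again earns 60 µl. Errors or omissions in either phase abort the
trial into a time-out; house-light polarity is inverted relative to the
5-CSRTT (off during the task, on during time-outs). Two open points were
settled as follows: the paradigm needs an ITI even though none is part of
its headline parameters, so an `iti_ms` field (default 5 s) was added; and
pokes during that ITI are logged but not scored, since no premature class is
defined for this task. Multi-hole choice configurations are not implemented;
the distractor-sampling rule is the hook where they would go.

**Opto/TTL schedules** anchor a pulse to a recurring task event — ITI onset
or reward-collection onset (receptacle entry after a correct response) —
with a configurable onset offset, duration and channel, emitting
TTL-high/TTL-low transitions into the log exactly like any other device.

## The virtual subject

The stochastic agent is the package's synthetic-data generator. It is
deliberately a *descriptive* model — independent draws per trial with no
learning, no satiation and no within-session drift — because its job is to
produce sessions whose true generating rates are known exactly:

* `p_respond` — probability of responding at all on a cued presentation;
* `p_correct` — probability the response goes to the cued hole, the
  remainder spread uniformly over the presented alternatives. Setting
  `p_correct = 0.2` in the 5-CSRTT makes the choice uniform over all five
  holes, the chance-level configuration;
* `premature_hazard` — a constant hazard (events/s) during the ITI, so the
  premature fraction over many trials of ITI $T$ is $1 - e^{-\lambda T}$;
* log-normal response and magazine latencies, and a fixed receptacle dwell.

The log-normal family is a modelling choice, not a claim about any
particular animal: it is positive, right-skewed and two-parameter, which is
what response-latency distributions in this field look like. Latency draws
are resampled (not censored) into the legal response window so that
`p_respond` keeps its meaning as the response probability. Defaults
(`p_respond = 0.8`, `p_correct = 0.8`, hazard 0.05/s, median response
latency 600 ms, median magazine latency 800 ms, dwell 1.5 s) were chosen
once as a plausible trained-mouse operating point and are not tuned to any
dataset.

Because the generator omits learning and fatigue, passing tests show that
the *machinery* — engines, logs, segmentation, metrics, scheduler, clock
fit — is correct at known ground truth; they do not show that any real
cohort behaves like the agent. Analyses of real logs in the same CSV
dialect are supported, but their scientific interpretation is the user's.

The scripted agent replays a fixed action list verbatim whatever the task
state. It exists so that every response class has a fixture whose full event
trace can be computed by hand; the test suite's classification oracle is
exactly such a set of hand traces.

## Event logs, segmentation, metrics

The log dialect is documented and versioned: comma-separated UTF-8 with `.`
decimals, `# `-prefixed metadata (paradigm, seed, duration, and one
`param:` line per protocol constant), a `time_ms,event,payload` header and a
closed event vocabulary. Carrying the protocol constants in the header is
what lets classification work from files alone: the response-window ends are
recovered from `sd_ms + lh_ms` rather than guessed from event patterns,
which would be ambiguous in the final millisecond of the limited hold. The
parser rejects exactly the documented malformations (unknown event names,
non-integer or decreasing timestamps) with the offending line number.

Trials run from one ITI start to the next; a final trial truncated before
its classification point is flagged incomplete and excluded from counts.
The metrics are the standard ones — accuracy
$100\,c/(c+i)$, omission and premature rates over all classified trials —
with undefined values (zero denominators) reported as `NA`, never 0 or 100,
so a degenerate session cannot silently satisfy or fail a training
criterion. Time-binned curves (default 3-min bins) recompute the same
formulas per bin, assigning trials by stimulus onset (premature trials,
which have none, by trial start). The response-share comparison is a plain
Pearson chi-square on the 2 × 4 class table, pooling out classes empty in
both conditions.

## Training-stage scheduling

Criteria are data, not code: per-stage thresholds on accuracy, omission
rate, correct count or reward count, plus a required number of consecutive
criterion-meeting sessions. Only the habituation rule — at least 30 rewards
in each of two consecutive sessions — is a fixed protocol constant and
ships hard-filled. The stage 1–5 parameters (SD ramping 20 s → 2 s at ITI
5 s) and thresholds in `default_training_schedule()` are labelled
placeholders: laboratories tune these values per cohort, so the schedule is
shipped as an editable object rather than pretending to known constants.

## Clock alignment

Behavioural and acquisition clocks are related by an affine model,
`received ≈ offset + drift · emitted`, fitted by least squares on matched
TTL pulse pairs. Over a 30-minute session, drift curvature is negligible at
the sub-millisecond scale, so no piecewise fitting is attempted — a
documented assumption, and the reason `|drift − 1| ≥ 1%` triggers a
warning. Matching is greedy nearest-neighbour after a coarse offset search:
candidate offsets come from pairings of the leading pulses and are scored by
how many pulses (probed from both ends of the train, which disambiguates
periodic pulse trains at their boundaries) find a partner within tolerance.
Received pulses beyond the tolerance raise an error listing their indices;
a configurable fraction of dropped pulses is tolerated. The simulator used
in tests generates the receiving side with known offset, drift, Gaussian
jitter and Bernoulli drops, so recovery can be asserted against ground
truth and fitted standard errors.

## Problem sizes and numerical tolerances

The test suite asserts stochastic properties at sizes chosen to make the
99% confidence intervals decisive while keeping a full run around a minute:
10,000 trials for the chance-level check, 2,000 for rate recovery, 100–500
pulses for clock fitting, and single-trial scripted fixtures for every exact
trace. Exact assertions (metric formulas, round-trips, determinism) use
identity, not tolerance, and the protocol constants — reward volumes,
window durations — are asserted exactly as read back from engine logs.

## Known limitations

* No hardware jitter: real boxes debounce beams and ramp pumps; the engine
  is ideal and instantaneous. No tolerance figures are modelled.
* The agent neither learns nor tires; training-simulation trajectories show
  scheduler logic, not acquisition curves. A time-varying `p_respond` hook
  would be the natural extension.
* Multi-hole choice-phase configurations and continuous-performance or
  rule-shift task variants are out of scope.
* The CSV dialect is this package's own documented format, not a clone of
  any vendor's or lab's file layout; external logs must be converted to it.
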