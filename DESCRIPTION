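Package: fivechoice
Title: Discrete-Event Simulation and Analysis of 5-Choice Operant Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A software-only operant-box system for 5-choice behavioural
    paradigms in rodents. Provides a millisecond-resolution discrete-event
    engine with virtual box devices (stimulus and house lights, reward pump,
    TTL lines), task builders for habituation, the 5-choice serial reaction
    time task (5-CSRTT, including attention and inter-trial-interval
    challenges) and the delayed-matching-to-position 5-choice spatial working
    memory task (5-CSWM), stochastic and scripted virtual subjects, a
    documented event-log CSV dialect with trial segmentation and response
    classification, standard performance metrics (accuracy, omission and
    premature rates, latencies, time-binned curves, response-share chi-square
    test), criterion-based training-stage scheduling, and affine clock
    alignment of behavioural timestamps with an acquisition system via shared
    TTL pulse trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
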