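# Example session configuration for `fivechoice run`.
# A trained-mouse-like stochastic subject on the 5-CSRTT baseline stage.
paradigm: 5csrtt
seed: 42
duration_min: 30
agent:
  p_respond: 0.8
  p_correct: 0.8
  premature_hazard: 0.05
out_dir: fivechoice_out
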