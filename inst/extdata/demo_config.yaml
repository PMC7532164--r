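# Demo pipeline configuration: a small synthetic registry with three planted
# progression rules, mined at the default published thresholds but with a
# reduced control ensemble so the demo runs in seconds.
seed: 42
simulate:
  n_patients: 5000
  rules:
    - source: I10
      target: N18
      multiplier: 25
      lag_mean: 2
      lag_sd: 0.8
    - source: I10
      target: E11
      multiplier: 15
      lag_mean: 1.5
      lag_sd: 0.8
    - source: N18
      target: D50
      multiplier: 20
      lag_mean: 1
      lag_sd: 0.8
thresholds:
  n_controls: 200
min_followers: 10
max_length: 6
min_patients: 5
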