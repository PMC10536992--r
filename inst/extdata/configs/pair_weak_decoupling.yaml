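# Weak decoupling protocol: run longer (5000 steps) and discard the first
# 2000 steps (about 0.5 ps) so the artificially decoupled fragments lose
# memory of the coupled start before the spectrum is accumulated.
fixture: coupled_pair_2d
seed: 1
scheme: SEF4
dt: 10
n_steps: 5000
discard_steps: 2000
decouple:
  - frame: normal_mode
    groups: [[1], [2]]
    alpha: 0.5
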