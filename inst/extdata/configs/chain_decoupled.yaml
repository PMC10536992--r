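# Full decoupling (alpha = 0) of the first two chain particles from the
# third, standard protocol: 3000 steps of 10 au, no decorrelation discard
# (the decoupling effect on this small system is strong from the start).
fixture: harmonic_chain_3
seed: 1
scheme: SEF2
dt: 10
n_steps: 3000
decouple:
  - frame: normal_mode
    groups: [[1, 2], [3]]
    alpha: 0.0
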