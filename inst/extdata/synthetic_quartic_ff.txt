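# Synthetic 3-mode quartic force field (atomic units, 1-based indices).
# Records: i i omega_i | i j k c_ijk | i j k l d_ijkl
# Coefficients are illustrative stand-ins, not fitted to any molecule.
1 1 0.005
2 2 0.010
3 3 0.017
1 1 2 2.0e-7
2 2 3 1.5e-7
1 2 3 1.0e-7
1 1 1 1 2.0e-9
2 2 2 2 2.0e-9
1 1 2 2 1.0e-9
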