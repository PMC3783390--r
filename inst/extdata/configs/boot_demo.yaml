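# Self-boot demonstration: single-society growth to full occupation.
n_o: 100
p_c_oo: 0.1
a_over_b: 60
p_m: 0.01
limina: 1.0
n_phases: 1500
n_reps: 50
seed: 1
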