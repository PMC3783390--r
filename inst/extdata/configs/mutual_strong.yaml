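# Mutually supporting derived society, situation 2: the printed support
# probabilities of 1.5 exceed 1 and are capped at 1 with a warning.
n_o: 100
p_c_oo: 0.1
n_d: 100
p_c_od: 1.5
p_c_do: 1.5
p_c_dd: 1.5
a_over_b: 100
p_m: 0.01
limina: 1.0
n_phases: 1500
n_reps: 50
seed: 1
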