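# Invasion by a more productive society: the original society goes extinct.
n_o: 100
p_c_oo: 0.1
n_i: 100
p_c_ii: 0.125
a_over_b: 100
p_m: 0.01
limina: 1.0
event_phase: 51
n_phases: 300
n_reps: 50
seed: 1
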