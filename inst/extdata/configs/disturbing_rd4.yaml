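# Pulse disturbance of severity r_d = 4 striking a steady-state society.
n_o: 100
p_c_oo: 0.1
a_over_b: 100
p_m: 0.01
limina: 1.0
r_d: 4
event_phase: 51
n_phases: 600
n_reps: 50
seed: 1
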