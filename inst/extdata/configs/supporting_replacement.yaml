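# Parasitic supporting, combination 3: the derived society also supports
# itself and replaces the original after its ruin.
n_o: 100
p_c_oo: 0.1
n_d: 200
p_c_od: 0.2
p_c_dd: 0.05
a_over_b: 100
p_m: 0.01
limina: 1.0
n_phases: 2000
n_reps: 50
seed: 1
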