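# Cross-linking sweep: physiological grid for the STC analysis.
kind: crosslink_sweep
Ka_pM_inv: [1.0e-7, 1.0e-5, 1.0e-3]
Aga0_pM: [0.1, 12, 1500]
specific_fraction: [1.0e-7, 1.0e-6, 1.0e-5, 1.0e-4, 1.0e-3, 1.0e-2]
s: [2, 5, 10]
valency: 100
k_on: 8.64e-3
decay_base: 0.5
t_end: 100
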