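# The three low-affinity/high-affinity conditions across four dose levels.
kind: ada
reference_by_dose: low_affinity
doses_mg: [40, 4, 0.4, 0.04]
scenarios:
  - {name: low_affinity, IR_mult: 1, epitopes_kd_nM: [1230, 850]}
  - {name: low_affinity_ir_x16.6, IR_mult: 16.6, epitopes_kd_nM: [1230, 850]}
  - {name: plus_high_affinity, IR_mult: 1, epitopes_kd_nM: [1230, 850, 38]}
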