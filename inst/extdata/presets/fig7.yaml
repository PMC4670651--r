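# Low-affinity baseline (1230 and 850 nM), the 16.6x internalization
# perturbation, and the induced high-affinity 38 nM epitope.
kind: ada
reference: low_affinity
scenarios:
  - {name: low_affinity, IR_mult: 1, epitopes_kd_nM: [1230, 850]}
  - {name: low_affinity_ir_x16.6, IR_mult: 16.6, epitopes_kd_nM: [1230, 850]}
  - {name: plus_high_affinity, IR_mult: 1, epitopes_kd_nM: [1230, 850, 38]}
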