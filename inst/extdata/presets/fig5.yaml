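# Antigen-processing perturbations with the two high-affinity epitopes
# (123 and 85 nM): baseline rates, 16.6x internalization, 16.6x degradation.
kind: ada
reference: baseline
scenarios:
  - {name: baseline, IR_mult: 1, DR_mult: 1, epitopes_kd_nM: [123, 85]}
  - {name: ir_x16.6, IR_mult: 16.6, DR_mult: 1, epitopes_kd_nM: [123, 85]}
  - {name: dr_x16.6, IR_mult: 1, DR_mult: 16.6, epitopes_kd_nM: [123, 85]}
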