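# Epitope-number perturbation on top of the two high-affinity epitopes.
# The Kd of the added third and fourth epitopes is not specified; the 200
# and 300 nM values are synthetic stand-ins in the reported nM range.
kind: ada
reference: two_epitopes
scenarios:
  - {name: two_epitopes, epitopes_kd_nM: [123, 85]}
  - {name: three_epitopes, epitopes_kd_nM: [123, 85, 200]}
  - {name: four_epitopes, epitopes_kd_nM: [123, 85, 200, 300]}
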