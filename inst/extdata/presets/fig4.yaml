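# Danger-signal ladder. 350 ng is the baseline calibration; 1750 ng is the
# 5-fold aggregate-enhanced level. Levels below baseline are a synthetic
# descending stand-in ladder (the exact low levels are not specified).
kind: ada
reference: ds_350
scenarios:
  - {name: ds_1750, danger_signal: 1750}
  - {name: ds_350, danger_signal: 350}
  - {name: ds_175, danger_signal: 175}
  - {name: ds_70, danger_signal: 70}
  - {name: ds_35, danger_signal: 35}
  - {name: ds_7, danger_signal: 7}
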