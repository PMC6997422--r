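# Example scenario grid for `ksref simulate` / run_scenario().
# Each entry is either an analyte preset with overrides or an explicit
# physiological/abnormal pair; margins are optional per-scenario.
scenarios:
  - name: hb_clean
    analyte: hemoglobin
    cycles: 10
    margins: {lower: [11.8, 12.2], upper: [15.8, 16.2]}
  - name: hb_low20
    analyte: hemoglobin
    abnormal_fraction: 0.20
    abnormal: {family: gaussian, p2_5: 8.0, p97_5: 12.0}
    cycles: 10
    margins: {lower: [11.8, 12.2], upper: [15.8, 16.2]}
  - name: tsh_high10
    analyte: tsh
    abnormal_fraction: 0.10
    abnormal: {family: gaussian, p2_5: 4.5, p97_5: 12.0}
    cycles: 5
    margins: {lower: [0.2, 0.3], upper: [3.8, 4.2]}
  - name: ggt_high10
    analyte: ggt
    abnormal_fraction: 0.10
    abnormal: {family: lognormal, p2_5: 40, p97_5: 300}
    cycles: 5
    margins: {lower: [8, 12], upper: [48, 52]}
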