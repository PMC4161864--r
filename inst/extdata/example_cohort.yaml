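label_map:
  ctrl_01: control
  ctrl_02: control
  ctrl_03: control
  ctrl_04: control
  ctrl_05: control
  pat_01: patient
  pat_02: patient
  pat_03: patient
  pat_04: patient
  pat_05: patient
normalization:
  timing: before_fe
excluded_features: []
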