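{
  "description": "Published per-quarter emotional-channel selections (second-order blind identification run) used as a worked example for the channel-intersection step.",
  "Q1": ["Fp1", "Fz", "F4", "F3", "F8", "Cz", "P4", "Pz", "P3", "O2"],
  "Q2": ["Pz", "P4", "P3", "O2", "Cz", "F3"],
  "Q3": ["F3", "T4", "C3", "T6", "P3", "T5", "Cz", "O2"],
  "Q4": ["P3", "Cz", "Pz", "P4", "O1", "O2", "T6", "T5", "F3"]
}
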