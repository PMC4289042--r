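{
  "1": {"lobe": "frontal",   "hemisphere": "left"},
  "2": {"lobe": "parietal",  "hemisphere": "left"},
  "3": {"lobe": "temporal",  "hemisphere": "left"},
  "4": {"lobe": "occipital", "hemisphere": "left"},
  "5": {"lobe": "frontal",   "hemisphere": "right"},
  "6": {"lobe": "parietal",  "hemisphere": "right"},
  "7": {"lobe": "temporal",  "hemisphere": "right"},
  "8": {"lobe": "occipital", "hemisphere": "right"}
}
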