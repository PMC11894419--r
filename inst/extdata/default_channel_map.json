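{
  "description": "EMG channel to MTU allocation: weights per MTU sum to 1; left channels drive left MTUs, right drive right.",
  "map": {
    "iliocostalis_l":         {"IL_L":   1.0},
    "iliocostalis_r":         {"IL_R":   1.0},
    "longissimus_lumbar_l":   {"LTpL_L": 1.0},
    "longissimus_lumbar_r":   {"LTpL_R": 1.0},
    "longissimus_thoracic_l": {"LTpT_L": 1.0},
    "longissimus_thoracic_r": {"LTpT_R": 1.0},
    "rectus_abdominis_l":     {"RA_L":   1.0},
    "rectus_abdominis_r":     {"RA_R":   1.0}
  }
}
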