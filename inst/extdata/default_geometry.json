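{
  "description": "Reduced bilateral trunk geometry: analytic length law L(theta) = L0 - r0*theta - r1*theta^2/2, moment arm r(theta) = r0 + r1*theta (extension-positive), axial projection coefficient c.",
  "domain": [-0.2, 1.3],
  "muscles": [
    {"name": "iliocostalis",          "group": "extensor", "L0": 0.28, "r0": 0.055, "r1": -0.005, "c": 0.95},
    {"name": "longissimus_lumbar",    "group": "extensor", "L0": 0.24, "r0": 0.055, "r1": -0.006, "c": 0.95},
    {"name": "longissimus_thoracic",  "group": "extensor", "L0": 0.34, "r0": 0.050, "r1": -0.003, "c": 0.95},
    {"name": "rectus_abdominis",      "group": "flexor",   "L0": 0.32, "r0": -0.080, "r1": 0.006, "c": 0.90}
  ]
}
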