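{
  "description": "Default Hill-type MTU parameters for the reduced trunk model. F_max N, l_opt m, l_ts m, phi_opt rad, beta damping, v_max optimal lengths/s, gamma active force-length width, k_pe passive exponent, eps0 passive strain at F_max, A activation shape factor.",
  "defaults": {"beta": 0.1, "v_max": 10, "gamma": 0.45, "k_pe": 4.0, "eps0": 0.6, "A": -1.5},
  "mtus": [
    {"name": "iliocostalis_l",         "F_max": 2000, "l_opt": 0.16, "l_ts": 0.12080, "phi_opt": 0.10},
    {"name": "iliocostalis_r",         "F_max": 2000, "l_opt": 0.16, "l_ts": 0.12080, "phi_opt": 0.10},
    {"name": "longissimus_lumbar_l",   "F_max": 2200, "l_opt": 0.15, "l_ts": 0.09061, "phi_opt": 0.09},
    {"name": "longissimus_lumbar_r",   "F_max": 2200, "l_opt": 0.15, "l_ts": 0.09061, "phi_opt": 0.09},
    {"name": "longissimus_thoracic_l", "F_max": 1800, "l_opt": 0.15, "l_ts": 0.19108, "phi_opt": 0.12},
    {"name": "longissimus_thoracic_r", "F_max": 1800, "l_opt": 0.15, "l_ts": 0.19108, "phi_opt": 0.12},
    {"name": "rectus_abdominis_l",     "F_max": 900,  "l_opt": 0.30, "l_ts": 0.02000, "phi_opt": 0.0},
    {"name": "rectus_abdominis_r",     "F_max": 900,  "l_opt": 0.30, "l_ts": 0.02000, "phi_opt": 0.0}
  ]
}
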