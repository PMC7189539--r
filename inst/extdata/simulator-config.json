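{
  "population": {
    "ischial_row": [
      19.5,
      20.5
    ],
    "thigh_row": [
      8,
      10
    ],
    "ischial_halfwidth": [
      3.5,
      6.0
    ],
    "thigh_halfwidth": [
      3.0,
      5.5
    ],
    "col_jitter": 0.3,
    "ischial_amplitude": [
      95,
      105
    ],
    "thigh_amplitude": [
      43,
      47
    ],
    "side_asymmetry": 0.01,
    "ischial_sigma": [
      2.4,
      2.8
    ],
    "thigh_sigma": [
      3.0,
      3.6
    ],
    "weight_scale": [
      400,
      800
    ]
  },
  "blob_aspect": {
    "ischial": 1.2,
    "thigh": 1.9
  },
  "effects": {
    "delta_ap_max": 6.0,
    "delta_ml_max": 5.0,
    "rho_tlf": 0.5,
    "rho_tr": 0.5,
    "rho_se": 0.35,
    "sigma_se": 0.15
  },
  "reach": {
    "period_s": 4.0,
    "excursion": {
      "back_and_forth": {
        "ap": 1.2,
        "ml": 0.1
      },
      "side_to_side": {
        "ap": 0.1,
        "ml": 0.3
      },
      "up_and_down": {
        "ap": 0.5,
        "ml": 0.15
      }
    }
  },
  "noise": {
    "multiplicative_sd": 0.05,
    "additive_sd_frac_peak": 0.01,
    "dropout_prob": 0.005
  },
  "load_jitter": 0.02,
  "duration_s": 4.0,
  "magnitude_range": [
    0.4,
    1.0
  ]
}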