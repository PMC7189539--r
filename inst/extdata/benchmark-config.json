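{
  "simulator": {
    "n_subjects": 8,
    "reps_per_cell": 15
  },
  "features": {
    "mirror": true
  },
  "classifier": {
    "c_exp": [-3, -1, 1, 3, 5, 7],
    "gamma_exp": [-7, -5, -3, -1, 1, 3],
    "inner_folds": 5
  },
  "stream": {
    "window_len": 50,
    "stride": 10,
    "smoothing_k": 5,
    "debounce_m": 3,
    "close_m": 3
  },
  "n_stream_holdout": 2,
  "seed": 20260911
}
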