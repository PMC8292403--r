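{
  "n_participants": 3,
  "noise_sd": 0.02,
  "nmf": {
    "n_restarts": 10,
    "n_folds": 5,
    "n_reps": 10,
    "threshold": 90,
    "n_range": [1, 2, 3, 4, 5, 6],
    "cv_restarts": 1
  },
  "clustering": { "k_range": [2, 3, 4, 5, 6], "n_init": 25 },
  "tensor": { "n_restarts": 5 },
  "bootstrap": { "n_boot": 2000, "alpha": 0.05 },
  "seed": 1
}
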