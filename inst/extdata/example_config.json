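{
  "seed": 1,
  "environment": {
    "c_source": 35.3,
    "c_sink": 5.3,
    "par_min": 0.1,
    "par_max": 45,
    "n_rows": 8,
    "n_cols": 8
  },
  "true_params": {
    "mu_max": 2.4,
    "L0": 50.8,
    "K_L": 57.2,
    "N0": 0,
    "K_N": 2.8
  },
  "simulation": {
    "duration_days": 7,
    "sample_interval_h": 4,
    "n_replicates": 3,
    "seeding": {"min_cells": 1, "max_cells": 6, "p_empty": 0.05},
    "noise": {"intensity_cv": 0.05, "background_level": 100, "background_sd": 5},
    "gain": 1000
  },
  "extraction": {"n": 9, "min_time_days": 1.3, "k": 4},
  "fitting": {"form": "multiplicative_storage", "acetate": true, "B": 1000}
}
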