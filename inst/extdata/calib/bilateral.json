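{
  "algorithm": "bilateral",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "sigma_int": 0.05,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.15,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.25,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.4,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.4,
      "sigma_sp": 1.5
    }
  ],
  "coeffs": [
    {
      "sigma_int": -0.0295825771324862,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 3.96009852216749,
      "sigma_sp": 6.94838833982328e-15
    },
    {
      "sigma_int": -8.77106559502203,
      "sigma_sp": -2.51223193979881e-14
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "sigma_int": 0.05,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.1,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.15,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.25,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.4,
      "sigma_sp": 1.5
    },
    {
      "sigma_int": 0.05,
      "sigma_sp": 3
    },
    {
      "sigma_int": 0.1,
      "sigma_sp": 3
    },
    {
      "sigma_int": 0.15,
      "sigma_sp": 3
    },
    {
      "sigma_int": 0.25,
      "sigma_sp": 3
    },
    {
      "sigma_int": 0.4,
      "sigma_sp": 3
    }
  ],
  "fixed_params": [],
  "seed": 100,
  "provenance": {
    "benchmark": "phantoms: membranes x2 (seeds 11,12), sarcomere, filaments (seed 13)",
    "shape": [128, 128],
    "K": 4,
    "base_seed": 100
  }
}
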