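{
  "algorithm": "nlm",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "h": 0.05
    },
    {
      "h": 0.23
    },
    {
      "h": 0.5
    },
    {
      "h": 0.7
    },
    {
      "h": 0.7
    }
  ],
  "coeffs": [
    {
      "h": -0.129346642468239
    },
    {
      "h": 8.66893267651888
    },
    {
      "h": -22.2959121942788
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "h": 0.02
    },
    {
      "h": 0.05
    },
    {
      "h": 0.1
    },
    {
      "h": 0.15
    },
    {
      "h": 0.23
    },
    {
      "h": 0.35
    },
    {
      "h": 0.5
    },
    {
      "h": 0.7
    }
  ],
  "fixed_params": {
    "B": 4,
    "W": 5
  },
  "seed": 100,
  "provenance": {
    "benchmark": "phantoms: membranes x2 (seeds 11,12), sarcomere, filaments (seed 13)",
    "shape": [128, 128],
    "K": 4,
    "base_seed": 100
  }
}
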