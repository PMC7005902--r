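{
  "algorithm": "nlm_deconv",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "h": 0.05,
      "lambda": 0.01
    },
    {
      "h": 0.15,
      "lambda": 0.05
    },
    {
      "h": 0.5,
      "lambda": 0.05
    },
    {
      "h": 0.5,
      "lambda": 0.15
    },
    {
      "h": 0.5,
      "lambda": 0.15
    }
  ],
  "coeffs": [
    {
      "h": -0.134936479128856,
      "lambda": -0.00680580762250451
    },
    {
      "h": 8.31018062397372,
      "lambda": 0.913300492610837
    },
    {
      "h": -25.8171290294702,
      "lambda": -0.409644801659321
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "h": 0.05,
      "lambda": 0.01
    },
    {
      "h": 0.15,
      "lambda": 0.01
    },
    {
      "h": 0.3,
      "lambda": 0.01
    },
    {
      "h": 0.5,
      "lambda": 0.01
    },
    {
      "h": 0.05,
      "lambda": 0.05
    },
    {
      "h": 0.15,
      "lambda": 0.05
    },
    {
      "h": 0.3,
      "lambda": 0.05
    },
    {
      "h": 0.5,
      "lambda": 0.05
    },
    {
      "h": 0.05,
      "lambda": 0.15
    },
    {
      "h": 0.15,
      "lambda": 0.15
    },
    {
      "h": 0.3,
      "lambda": 0.15
    },
    {
      "h": 0.5,
      "lambda": 0.15
    }
  ],
  "fixed_params": {
    "B": 4,
    "W": 5,
    "sigma_psf": 0,
    "n_iter": 20
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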