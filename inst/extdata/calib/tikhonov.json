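{
  "algorithm": "tikhonov",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "lambda": 0.25
    },
    {
      "lambda": 0.25
    },
    {
      "lambda": 0.5
    },
    {
      "lambda": 1.5
    },
    {
      "lambda": 6
    }
  ],
  "coeffs": [
    {
      "lambda": 1.29537205081669
    },
    {
      "lambda": -44.4934318555008
    },
    {
      "lambda": 333.683346296776
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "lambda": 0.25
    },
    {
      "lambda": 0.5
    },
    {
      "lambda": 1
    },
    {
      "lambda": 1.5
    },
    {
      "lambda": 2.5
    },
    {
      "lambda": 4
    },
    {
      "lambda": 6
    },
    {
      "lambda": 9
    }
  ],
  "fixed_params": {
    "sigma_psf": 0,
    "n_iter": 10
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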