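{
  "algorithm": "tv",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "lambda": 0.05
    },
    {
      "lambda": 0.1
    },
    {
      "lambda": 0.2
    },
    {
      "lambda": 0.4
    },
    {
      "lambda": 0.4
    }
  ],
  "coeffs": [
    {
      "lambda": 0.00365853658536591
    },
    {
      "lambda": 2.17636022514071
    }
  ],
  "degree": 1,
  "K": 4,
  "param_grid": [
    {
      "lambda": 0.01
    },
    {
      "lambda": 0.02
    },
    {
      "lambda": 0.05
    },
    {
      "lambda": 0.1
    },
    {
      "lambda": 0.2
    },
    {
      "lambda": 0.4
    }
  ],
  "fixed_params": {
    "n_iter": 100,
    "eps": 0.001
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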