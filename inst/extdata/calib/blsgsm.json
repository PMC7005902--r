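{
  "algorithm": "blsgsm",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "sigma_n": 0.02
    },
    {
      "sigma_n": 0.05
    },
    {
      "sigma_n": 0.08
    },
    {
      "sigma_n": 0.16
    },
    {
      "sigma_n": 0.22
    }
  ],
  "coeffs": [
    {
      "sigma_n": 0.00921960072595284
    },
    {
      "sigma_n": 0.567848932676519
    },
    {
      "sigma_n": 2.50159882464783
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "sigma_n": 0.02
    },
    {
      "sigma_n": 0.05
    },
    {
      "sigma_n": 0.08
    },
    {
      "sigma_n": 0.12
    },
    {
      "sigma_n": 0.16
    },
    {
      "sigma_n": 0.22
    }
  ],
  "fixed_params": {
    "J": 3,
    "K_orient": 8
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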