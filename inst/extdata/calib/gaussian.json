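{
  "algorithm": "gaussian",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "sigma": 0.5
    },
    {
      "sigma": 0.5
    },
    {
      "sigma": 1
    },
    {
      "sigma": 1.25
    },
    {
      "sigma": 1.5
    }
  ],
  "coeffs": [
    {
      "sigma": 0.323170731707317
    },
    {
      "sigma": 6.02720450281426
    }
  ],
  "degree": 1,
  "K": 4,
  "param_grid": [
    {
      "sigma": 0.5
    },
    {
      "sigma": 0.75
    },
    {
      "sigma": 1
    },
    {
      "sigma": 1.25
    },
    {
      "sigma": 1.5
    },
    {
      "sigma": 1.75
    },
    {
      "sigma": 2
    },
    {
      "sigma": 2.5
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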