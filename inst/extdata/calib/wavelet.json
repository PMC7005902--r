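{
  "algorithm": "wavelet",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "T": 0.02
    },
    {
      "T": 0.05
    },
    {
      "T": 0.12
    },
    {
      "T": 0.16
    },
    {
      "T": 0.3
    }
  ],
  "coeffs": [
    {
      "T": 0.0169872958257713
    },
    {
      "T": 0.337963875205255
    },
    {
      "T": 5.16342580589404
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "T": 0.02
    },
    {
      "T": 0.05
    },
    {
      "T": 0.08
    },
    {
      "T": 0.12
    },
    {
      "T": 0.16
    },
    {
      "T": 0.22
    },
    {
      "T": 0.3
    },
    {
      "T": 0.4
    }
  ],
  "fixed_params": {
    "n_scales": 6
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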