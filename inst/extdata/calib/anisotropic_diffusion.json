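{
  "algorithm": "anisotropic_diffusion",
  "sigma_grid": [0.02, 0.05, 0.1, 0.15, 0.2],
  "theta_grid": [
    {
      "kappa": 0.05,
      "n_iter": 8
    },
    {
      "kappa": 0.18,
      "n_iter": 8
    },
    {
      "kappa": 0.3,
      "n_iter": 8
    },
    {
      "kappa": 0.5,
      "n_iter": 8
    },
    {
      "kappa": 0.5,
      "n_iter": 8
    }
  ],
  "coeffs": [
    {
      "kappa": -0.0491288566243192,
      "n_iter": 7.99999999999999
    },
    {
      "kappa": 4.97254515599343,
      "n_iter": 5.94205272520218e-14
    },
    {
      "kappa": -10.7437559415781,
      "n_iter": -2.14838519583969e-13
    }
  ],
  "degree": 2,
  "K": 4,
  "param_grid": [
    {
      "kappa": 0.05,
      "n_iter": 3
    },
    {
      "kappa": 0.1,
      "n_iter": 3
    },
    {
      "kappa": 0.18,
      "n_iter": 3
    },
    {
      "kappa": 0.3,
      "n_iter": 3
    },
    {
      "kappa": 0.5,
      "n_iter": 3
    },
    {
      "kappa": 0.05,
      "n_iter": 5
    },
    {
      "kappa": 0.1,
      "n_iter": 5
    },
    {
      "kappa": 0.18,
      "n_iter": 5
    },
    {
      "kappa": 0.3,
      "n_iter": 5
    },
    {
      "kappa": 0.5,
      "n_iter": 5
    },
    {
      "kappa": 0.05,
      "n_iter": 8
    },
    {
      "kappa": 0.1,
      "n_iter": 8
    },
    {
      "kappa": 0.18,
      "n_iter": 8
    },
    {
      "kappa": 0.3,
      "n_iter": 8
    },
    {
      "kappa": 0.5,
      "n_iter": 8
    }
  ],
  "fixed_params": {
    "eta": 0.07,
    "variant": 1
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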