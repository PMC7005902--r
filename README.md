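# emrestore

Headless restoration engine for volume electron microscopy (and any 2D/3D
grayscale imaging). Slice-and-view EM (SBF-SEM, FIB-SEM) trades acquisition
speed against noise through the beam dwell time: shorter dwell means faster
stacks and less charging, but noisier images that hurt visualization,
segmentation and counting. `emrestore` implements the restoration toolbox
that makes the fast-acquisition route practical — noise/blur estimation,
automatic parameter initialization, eight denoising/deconvolution
algorithms, slice-by-slice batch processing with reproducible run metadata,
and the evaluation utilities needed to verify that restoration actually
helps downstream analysis.

## Model

The acquired image is modeled as

    y = H x + n

with `H` an isotropic Gaussian point-spread function (σ_psf pixels) applied
per slice and `n` i.i.d. mean-zero Gaussian noise of standard deviation σ on
the [0, 1] intensity scale. The noise level is estimated robustly by a
median-absolute-deviation estimator (raw and wavelet-domain variants), blur
by the variation lost under 1D smoothing. Restoration algorithms:

| algorithm | idea | key parameters |
|---|---|---|
| `gaussian` | linear smoothing, fixed 7×7 window | σ_g |
| `wavelet` | dual-tree complex wavelet soft thresholding | T, scales |
| `anisotropic_diffusion` | Perona–Malik edge-stopping diffusion | η, N, κ |
| `bilateral` | range-weighted mean, fixed 15×15 window | σ_sp, σ_int |
| `tikhonov` | ‖y−Hx‖² + λ‖Lx‖² (Laplacian prior), CG solver | λ, σ_psf, N |
| `tv` | ε-smoothed total variation (ROF) | λ, N |
| `blsgsm` | Bayesian least squares on Gaussian scale mixtures over a steerable pyramid | σ_n, J, K |
| `nlm` / `nlm_deconv` | patch-similarity weighted averaging / quadratic nonlocal prior deconvolution | h, B, W (+λ, σ_psf, N) |

Parameters are auto-initialized from the estimated noise level via shipped
calibration tables: per-noise-level optima found by grid search on phantom
benchmarks and fitted as linear/quadratic polynomials in σ (see the
methods vignette, `vignettes/emrestore-methods.Rmd`).

Because no external dataset is required, the package generates EM-like
phantoms with exact ground truth: membrane networks (Voronoi cells with
dark boundaries), sarcomere A/I band patterns, and filament cross-sections
with known object counts.

## Worked example

```r
library(emrestore)

# ground truth + degraded acquisition (sigma = 0.1 additive noise)
ph <- phantom_membranes(c(256L, 256L), n_cells = 20L, seed = 1L)
y  <- degrade(ph$image, degradation_model(sigma_psf = 0, sigma_noise = 0.1,
                                          seed = 2L))

# estimate the noise level, auto-initialize NLM, restore
sigma_hat <- estimate_noise_mad(get_slice(y), "mad_wavelet")$sigma_hat
spec <- algorithm_spec("nlm", auto_params("nlm", sigma_hat))
res  <- apply_to_stack(y, spec)

cat(sprintf("sigma_hat = %.4f\n", sigma_hat))
cat(sprintf("PSNR noisy    : %.2f dB\n", psnr(y$data, ph$image$data)))
cat(sprintf("PSNR restored : %.2f dB\n", psnr(res$volume$data, ph$image$data)))

# restoration helps simple downstream segmentation
d_raw <- dice(threshold_segment(get_slice(y), -Inf, 0.5), ph$mask)
d_den <- dice(threshold_segment(get_slice(res$volume), -Inf, 0.5), ph$mask)
cat(sprintf("Dice raw %.3f -> denoised %.3f\n", d_raw, d_den))

# write the result with its reproducibility record embedded in the TIFF
write_volume(res$volume, "denoised.tif", record = res$record)
```

Output:

```
sigma_hat = 0.1055
PSNR noisy    : 19.98 dB
PSNR restored : 27.86 dB
Dice raw 0.976 -> denoised 0.998
```

`sigma_hat` is the wavelet-MAD estimate of the injected noise level; the
PSNR lines show the restoration gain over the acquisition; the Dice line
shows intensity-threshold membrane segmentation agreeing better with
ground truth after denoising. The record embedded in `denoised.tif` is
sufficient to re-run the restoration bit-identically.

A thin CLI over the same functions is installed with the package
(`inst/scripts/emrestore`): subcommands `estimate`, `denoise`, `preview`,
`calibrate`, `phantom`, `evaluate`, `plan`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the acquisition-throughput worked example from its printed
inputs (500 frames of 10⁸ pixels at 4 µs vs 1 µs dwell, 499 slicings of
18 s each) via `acquisition_time()`, runs an end-to-end
estimate→calibrate→denoise check, and writes the resulting numbers as
JSON. The broader acceptance properties (oracle equivalences, estimator
accuracy, fixed points, denoising efficacy, calibration recovery, the
denoise-then-segment trend, workflow contracts) run as part of the test
suite in `tests/testthat/test-acceptance.R`.
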