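---
title: "Restoration methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoration methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emrestore)
```

# Scope and model

`emrestore` is a headless restoration engine for slice-and-view volume
electron microscopy (SBF-SEM / FIB-SEM) and, more generally, any 2D/3D
grayscale modality. The acquisition is modeled as

$$ y = Hx + n, $$

where $x$ is the degradation-free image on the unit intensity scale, $H$ an
isotropic 2D Gaussian point-spread function of width $\sigma_{psf}$ pixels,
and $n$ i.i.d. mean-zero Gaussian noise of standard deviation
$\sigma$ (constant variance per pixel). Volumes are processed slice by
slice: each $z$-plane is restored independently by a 2D algorithm, which is
the standard practical compromise for anisotropic slice-and-view stacks.
All computation is done in floating point; integer acquisitions (8/16-bit)
are first mapped to $[0,1]$ by their dtype range.

Assumptions worth making explicit:

* the PSF family is Gaussian and spatially invariant — the single exposed
  $\sigma$ of the deconvolution modes implies a one-parameter radial
  kernel, and Gaussian is the natural choice for SEM probe blur;
* the noise is additive with constant variance; Poisson or mixed
  Poisson-Gaussian statistics of very low-dose imaging are out of scope;
* spatial convolutions use mirror (reflect) boundary handling, which avoids
  the dark-frame artifacts a zero-padded boundary produces on block-face
  images.

# Noise and blur estimation

Two robust noise estimates are provided. The *raw MAD*
$\hat\sigma = \mathrm{med}(|y - \mathrm{med}(y)|)$ is the literal robust
scale of the image: it is reported for diagnostics but conflates texture
with noise (on pure $N(0,\sigma)$ noise it converges to $0.6745\,\sigma$,
the median of the half-normal). The *wavelet MAD* applies the same
statistic to the finest diagonal wavelet detail (a decimated Haar detail,
which passes i.i.d. noise at unit gain while suppressing smooth structure)
and divides by 0.6745; this is the Gaussian-consistent variant and is what
automatic parameter initialization uses. On textured phantoms it recovers
injected $\sigma \in [0.02, 0.2]$ within 5%.

Blur is scored in $[0,1]$ by comparing pixel variation before and after a
length-9 moving average: variation that survives smoothing is attributed to
blur. Absolute first differences are used in both the numerator and the
normalization; with signed differences the score can leave $[0,1]$, so the
absolute-value reading of the printed formulas is adopted deliberately.

# The eight restoration algorithms

* **Gaussian filter** — normalized Gaussian kernel on a fixed 7×7 window
  (only $\sigma_g$ is tunable, matching the plugin's fixed window).
* **Wavelet soft thresholding** — a 2D dual-tree complex wavelet transform
  per slice, 6 scales by default; complex detail magnitudes are shrunk by
  $\tau(z) = \mathrm{sign}(z)\max(|z|-T,0)$ with phase preserved. The dual
  tree is built from the closed-form orthonormal Daubechies 4-tap filter
  bank for tree A and its time reverse for tree B (time reversal is exactly
  the relationship between the two trees in the q-shift design; the
  published q-shift coefficient tables are numerical design products and
  are not reproduced here). Each tree is exactly perfect-reconstruction, so
  the $T=0$ round trip is exact to machine precision; shift invariance is
  approximate. The settings list names a 3D transform while processing is
  slice-by-slice 2D; the 2D transform per slice is implemented and the
  contradiction is resolved in favor of the slice-by-slice statement.
* **Anisotropic diffusion** — explicit Perona–Malik iterations on a
  4-neighbor stencil with per-arm conductances, exponential
  $e^{-(s/\kappa)^2}$ (default) or rational $1/(1+(s/\kappa)^2)$; stability
  requires $\eta \le 0.25$ and the constructor enforces it. With
  $\kappa \to \infty$ one step reduces to the linear heat step, which is a
  tested limit.
* **Bilateral filter** — fixed 15×15 window, spatial and intensity
  Gaussians. As printed, the estimator has no normalizing denominator;
  weights are normalized to unit sum per pixel — without this a constant
  image is not a fixed point — and the normalization is documented as a
  deliberate correction.
* **Tikhonov denoising/deconvolution** — minimizes
  $\|y-Hx\|^2 + \lambda\|Lx\|^2$ with $L$ the 5-point Laplacian, solved by
  conjugate gradients on the normal equations. Periodic boundaries make the
  FFT closed form exact, which serves as the oracle; for real data the
  image is mirror-padded first and cropped after, suppressing wrap-around.
  $\lambda$ weights the prior term (the natural reading of the energy).
* **Total variation** — the 2D $\epsilon$-smoothed ROF energy
  ($\epsilon = 10^{-3}$), with the $D_z$ term dropped per slice-by-slice
  processing. The minimizer is found by lagged-diffusivity
  majorize-minimize (IRLS) with warm-started inner CG rather than plain
  gradient descent: the smoothed TV term has curvature $\sim\lambda/\epsilon$
  in flat regions, which makes fixed-budget first-order descent hopeless at
  large $\lambda$ (it cannot reach the analytic constant-image limit within
  the advertised iteration count), while MM preserves the two properties
  that matter and are tested — a monotonically non-increasing objective and
  convergence to the large-$\lambda$ mean limit.
* **BLS-GSM** — steerable-pyramid decomposition ($J=3$ scales, 8
  orientations, undecimated), each subband's 3×3 coefficient neighborhoods
  modeled as Gaussian scale mixtures $v = \sqrt{z}\,u$. The pyramid is a
  self-inverting tight frame: raised-cosine radial bands times angular
  $\cos^{K-1}$ windows, normalized pointwise so the squared masks sum to
  one — reconstruction is exact by construction rather than by delicate
  constant-matching. $C_n$ is propagated analytically from $\hat\sigma$
  through each subband filter's autocorrelation; $C_u = \max(C_w - C_n, 0)$
  by eigenvalue clipping; the $z$ integral is a 13-point log-spaced mixture
  under a noninformative (uniform-in-$\log z$) prior normalized to mean 1.
  The neighborhood is purely spatial (no parent coefficient). Exact
  numerical parity with any specific published implementation is a
  non-goal; the tested contracts are the noise-free limit, determinism, and
  beating the best grid-searched Gaussian filter.
* **Nonlocal means (and deconvolution)** — patch weights
  $w_{ij} = \exp(-\tfrac12\|y_{N_i}-y_{N_j}\|^2/h)$ over a $(2W+1)^2$
  search window, raw squared patch distance (no per-pixel normalization)
  and $h$ on the unit intensity scale, so the printed damping values
  reproduce behavior only at the stated patch size. Border patches come
  from one symmetric mirror extension of the image. Deconvolution minimizes
  $\|y-Hx\|^2 + \lambda\sum_{ij}w_{ij}(x_i-x_j)^2$ with weights computed
  once on a nonlocal-means pilot of $y$ and held fixed; the pair sum is
  restricted to the search window (outside it the weights are numerically
  zero — a recorded sparsification). The objective is an exactly quadratic
  form, so the descent scheme is conjugate gradients initialized at $y$:
  monotone in the objective and matching a dense linear solve on small
  problems to $10^{-6}$.

# Automatic parameter initialization

For each algorithm, per-noise-level optimal parameters
$\theta_m = \arg\min_\theta \sum_k \|f_\theta(y_{k,m}) - x_k\|^2$ are found
by exhaustive grid search (grids ordered weakest smoothing first; ties break
toward the weakest setting), then each parameter is fitted as a degree-$q$
polynomial in $\sigma$ and predicted at the estimated noise level, clipped
into the searched bounds. Grid search — rather than a continuous optimizer
— was chosen so the exhaustive oracle in the tests is exact and the tables
are bit-reproducible. $q$ is selected automatically: quadratic is kept only
when it cuts the residual by more than 20% relative to linear.

The shipped tables (in `inst/extdata/calib/`, rebuilt by
`tools/build_calibration.R`) replace the original benchmark corpus of 100
real EM images with K = 4 phantom images at 128² degraded at
$\sigma_m \in \{0.02, 0.05, 0.10, 0.15, 0.20\}$ — a desk-scale stand-in
chosen so the whole calibration reruns in minutes; every table records its
provenance (phantom kinds, seeds, grid).

# Phantoms: what they emulate and what they do not

Three generators provide ground truth without any external data: Voronoi
cell partitions with dark membranes of configurable width (neuropil-like
tissue; the membrane mask is the boundary band, analogous to edges dilated
to the mean membrane width), alternating dark A-bands and bright I-bands of
striated muscle with smooth transitions, and non-overlapping bright
filament cross-sections with a known count. The membrane background carries
low-amplitude (0.05) smoothed Gaussian texture: on a perfectly flat
background every denoiser looks perfect, so the texture is what makes the
comparison honest. The phantoms do *not* emulate detector MTF, charging,
curtaining, or stain granularity — a green test establishes correctness of
the algorithms and the direction of the denoise-then-segment effect, not
field performance on real tissue.

Noise is never baked into a phantom; degradation is applied only through
the forward model, so every experiment controls $\sigma$ and the seed.

# Numerical choices and degenerate inputs

* Gaussian kernels truncate at $\lceil 4\sigma\rceil$ and renormalize to
  unit sum, so $H$ preserves the image mean.
* The degradation output is not clipped to $[0,1]$ (restoration inputs may
  legitimately exceed the range); clipping is an explicit export step.
* Constant images: every denoiser leaves them unchanged (tested); the blur
  estimator rejects them (the normalization of the blur score is a total
  variation, which vanishes).
* `em_wavelet` rejects scale counts deeper than the image supports and
  mirror-pads internally to a multiple of $2^{scales}$.
* Component counting is 8-connected (the particle-analysis default in 2D);
  threshold ranges are closed on both ends. The optional watershed split is
  seeded from 3×3 local maxima of the exact Euclidean distance transform,
  with maxima at distance $\le\sqrt2$ suppressed so a 1-px bridge between
  objects cannot seed its own region.
* Coordinates in the R API are 1-based with inclusive ROI bounds (the
  language's convention); the CLI speaks the same 1-based dialect.

# Reproducibility plumbing

`apply_to_stack()` returns a run record (algorithm, parameters, estimates,
slice range, input checksum, timestamp) that `write_volume()` embeds as
JSON in the TIFF ImageDescription tag; `read_volume()` restores it, and
re-running the recorded spec on the same input reproduces the output
bit-identically (tested). Denoised output is stored as float32; integer
export is an explicit lossy conversion. TIFF and PNG support is
implemented inside the package (baseline uncompressed grayscale TIFF,
minimal 8-bit PNG) because no image I/O package is assumed; both formats
are validated against independent readers.

# Known limitations

* Shift invariance of the dual-tree transform is approximate (see above);
  denoising quality, not coefficient-level parity with q-shift
  implementations, is the contract.
* BLS-GSM omits the parent (coarser-scale) coefficient from the
  neighborhood vector.
* TV deconvolution ($H \ne I$) is not offered, matching the advertised
  algorithm list; Tikhonov and NLM handle the deconvolution use cases.
* The throughput calculator takes frame and slicing counts at face value
  and reproduces the printed worked example; it does not model stage
  overhead or autofocus.
* All filters are single-threaded R; the design favors testability and
  exactness over the latency of a GPU implementation.
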