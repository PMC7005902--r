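#' Image volume container
#'
#' A light container for 2D/3D grayscale image data on the unit intensity
#' scale. Data are stored as a 3D array indexed \code{[y, x, z]}; a 2D image
#' is a volume with a single slice. All restoration algorithms operate on the
#' \code{[0, 1]} scale, so integer acquisitions (8/16-bit) must pass through
#' \code{\link{normalize_to_unit}} first.
#'
#' @param data numeric matrix (2D image) or 3D array \code{[y, x, z]}.
#' @param voxel_size optional numeric length-3 voxel size \code{(z, y, x)} in nm.
#' @param source_dtype original sample type, one of \code{"uint8"},
#'   \code{"uint16"}, \code{"float"}; kept for round-trip export.
#' @param metadata named list of provenance key/value pairs.
#' @return An object of class \code{em_volume}.
#' @export
em_volume <- function(data, voxel_size = NULL, source_dtype = "float",
                      metadata = list()) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop("`data` must be a matrix or a 3D array [y, x, z]")
  if (!all(is.finite(data)))
    stop("non-finite values in image data (NaN/Inf); clean the input first")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  structure(list(
    data = data,
    voxel_size = voxel_size,
    source_dtype = source_dtype,
    metadata = metadata
  ), class = "em_volume")
}

#' @export
print.em_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<em_volume> %d x %d x %d (y,x,z), range [%.4g, %.4g], dtype %s\n",
              d[1], d[2], d[3], min(x$data), max(x$data), x$source_dtype))
  invisible(x)
}

#' @export
dim.em_volume <- function(x) dim(x$data)

#' Extract a single slice as a matrix
#' @param volume an \code{em_volume}
#' @param z 1-based slice index
#' @return numeric matrix \code{[y, x]}
#' @export
get_slice <- function(volume, z = 1L) {
  stopifnot(inherits(volume, "em_volume"))
  d <- dim(volume$data)
  if (z < 1L || z > d[3]) stop("slice index out of range")
  volume$data[, , z, drop = TRUE]
}

as_volume_data <- function(x) {
  if (inherits(x, "em_volume")) return(x$data)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected em_volume, matrix or 3D array")
}

#' Normalize raw integer/float data to the unit intensity scale
#'
#' Integer data are mapped by \code{(raw - dtype_min) / (dtype_max - dtype_min)};
#' floating-point data are left untouched when already inside \code{[0, 1]}
#' and min-max scaled otherwise. The declared type is recorded so that a
#' lossy re-quantization for export can round-trip.
#'
#' @param raw numeric matrix or 3D array of raw samples.
#' @param declared_dtype one of \code{"uint8"}, \code{"uint16"}, \code{"float"}.
#' @param voxel_size,metadata passed to \code{\link{em_volume}}.
#' @return an \code{em_volume} with data in \code{[0, 1]}.
#' @export
normalize_to_unit <- function(raw, declared_dtype = c("uint8", "uint16", "float"),
                              voxel_size = NULL, metadata = list()) {
  declared_dtype <- match.arg(declared_dtype)
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  if (!all(is.finite(raw)))
    stop("non-finite values (NaN/Inf) in raw input; refusing to normalize")
  data <- switch(declared_dtype,
    uint8  = raw / 255,
    uint16 = raw / 65535,
    float  = {
      rng <- range(raw)
      if (rng[1] >= 0 && rng[2] <= 1) raw
      else if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
      else raw * 0
    })
  em_volume(data, voxel_size = voxel_size, source_dtype = declared_dtype,
            metadata = metadata)
}

#' Degradation model: Gaussian blur plus additive white Gaussian noise
#'
#' Forward model of the acquisition: \code{y = H x + n}, with \code{H} an
#' isotropic 2D Gaussian point-spread function applied slice by slice
#' (mirror boundary) and \code{n} i.i.d. mean-zero Gaussian noise of
#' standard deviation \code{sigma_noise} on the unit intensity scale.
#'
#' @param sigma_psf PSF standard deviation in pixels; 0 means no blur.
#' @param sigma_noise noise standard deviation on the \code{[0,1]} scale.
#' @param seed integer RNG seed making the noise realization reproducible.
#' @return an object of class \code{degradation_model}.
#' @export
degradation_model <- function(sigma_psf = 0, sigma_noise = 0, seed = 1L) {
  if (sigma_psf < 0 || sigma_noise < 0) stop("sigma_psf and sigma_noise must be >= 0")
  structure(list(sigma_psf = sigma_psf, sigma_noise = sigma_noise,
                 seed = as.integer(seed)),
            class = "degradation_model")
}

# truncated, unit-sum 1D Gaussian kernel; radius ceil(4*sigma)
gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- ceiling(4 * sigma)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# mirror (symmetric, edge included) padding of a matrix
mirror_pad <- function(m, py, px = py) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- reflect_index(seq_len(ny + 2 * py) - py, ny)
  ix <- reflect_index(seq_len(nx + 2 * px) - px, nx)
  m[iy, ix, drop = FALSE]
}

# symmetric reflection of arbitrary (possibly out-of-range) 1-based indices
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1) %% (2 * n)
  ifelse(p < n, p + 1, 2 * n - p)
}

# separable 2D convolution with mirror boundary, odd-length 1D kernels
conv2_sep_mirror <- function(m, ky, kx = ky) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- mirror_pad(m, ry, rx)
  if (ry > 0) {
    # convolve along rows (y): stats::filter runs down each column
    p <- stats::filter(p, filter = rev(ky), method = "convolution", sides = 2)
    p <- p[(ry + 1):(nrow(p) - ry), , drop = FALSE]
  }
  if (rx > 0) {
    p <- t(stats::filter(t(p), filter = rev(kx), method = "convolution", sides = 2))
    p <- p[, (rx + 1):(ncol(p) - rx), drop = FALSE]
  }
  matrix(as.numeric(p), nrow = nrow(m), ncol = ncol(m))
}

# Gaussian PSF blur of one slice, kernel truncated at ceil(4*sigma)
psf_blur <- function(m, sigma_psf) {
  if (sigma_psf <= 0) return(m)
  k <- gaussian_kernel_1d(sigma_psf)
  conv2_sep_mirror(m, k, k)
}

#' Apply the forward degradation model
#'
#' Blurs each slice with the model PSF and adds seeded i.i.d. Gaussian
#' noise. The result is deliberately \emph{not} clipped to \code{[0,1]}
#' (restoration inputs may exceed the unit range); set \code{clip = TRUE}
#' for export-bound data.
#'
#' @param x an \code{em_volume} (or matrix/array).
#' @param model a \code{\link{degradation_model}}.
#' @param clip clip the result into \code{[0,1]}?
#' @return an \code{em_volume} with degraded data.
#' @export
degrade <- function(x, model, clip = FALSE) {
  stopifnot(inherits(model, "degradation_model"))
  a <- as_volume_data(x)
  out <- a
  for (z in seq_len(dim(a)[3]))
    out[, , z] <- psf_blur(a[, , z], model$sigma_psf)
  if (model$sigma_noise > 0) {
    withr_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(model$seed)
    out <- out + array(stats::rnorm(length(out), 0, model$sigma_noise), dim = dim(out))
    if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  }
  if (clip) out <- pmin(pmax(out, 0), 1)
  md <- if (inherits(x, "em_volume")) x$metadata else list()
  md$degradation <- list(sigma_psf = model$sigma_psf,
                         sigma_noise = model$sigma_noise, seed = model$seed)
  em_volume(out, voxel_size = if (inherits(x, "em_volume")) x$voxel_size,
            source_dtype = "float", metadata = md)
}
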