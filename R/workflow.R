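# Algorithm specification, dispatch, ROI preview, slice-by-slice batch
# processing and acquisition-throughput arithmetic.

.alg_params <- list(
  gaussian              = c("sigma"),
  wavelet               = c("T", "n_scales"),
  anisotropic_diffusion = c("eta", "n_iter", "kappa", "variant"),
  bilateral             = c("sigma_sp", "sigma_int"),
  tikhonov              = c("lambda", "sigma_psf", "n_iter"),
  tv                    = c("lambda", "n_iter", "eps"),
  blsgsm                = c("sigma_n", "J", "K_orient"),
  nlm                   = c("h", "B", "W"),
  nlm_deconv            = c("h", "B", "W", "lambda", "sigma_psf", "n_iter")
)

#' Algorithm specification
#'
#' A serializable record of an algorithm identifier plus its full parameter
#' set; embedded in output metadata so any run can be reproduced exactly.
#' The parameter list must contain exactly the names the algorithm
#' requires. The diffusion \code{variant} is encoded numerically
#' (1 = exponential, 2 = rational) so that every parameter is a number.
#'
#' @param algorithm one of \code{gaussian}, \code{wavelet},
#'   \code{anisotropic_diffusion}, \code{bilateral}, \code{tikhonov},
#'   \code{tv}, \code{blsgsm}, \code{nlm}, \code{nlm_deconv}.
#' @param params named list of numeric parameters.
#' @param version spec version string.
#' @return an \code{algorithm_spec} object.
#' @export
algorithm_spec <- function(algorithm, params, version = "1.0") {
  if (!algorithm %in% names(.alg_params))
    stop(sprintf("unknown algorithm '%s'", algorithm))
  required <- .alg_params[[algorithm]]
  if (algorithm == "anisotropic_diffusion" && is.null(params$variant))
    params$variant <- 1
  params <- params[order(match(names(params), required))]
  if (!setequal(names(params), required))
    stop(sprintf("%s requires exactly params {%s}; got {%s}", algorithm,
                 paste(required, collapse = ", "),
                 paste(names(params), collapse = ", ")))
  if (!all(vapply(params, function(p) is.numeric(p) && length(p) == 1, TRUE)))
    stop("all parameters must be single numbers")
  structure(list(algorithm = algorithm, params = params, version = version),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("<algorithm_spec> %s(%s)\n", x$algorithm,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Run a restoration algorithm on a single slice
#'
#' Dispatches an \code{\link{algorithm_spec}} to the corresponding filter.
#'
#' @param image matrix or single-slice \code{em_volume}.
#' @param spec an \code{algorithm_spec}.
#' @return restored matrix.
#' @export
run_algorithm <- function(image, spec) {
  stopifnot(inherits(spec, "algorithm_spec"))
  m <- as_slice_matrix(image)
  p <- spec$params
  switch(spec$algorithm,
    gaussian = em_gaussian(m, p$sigma),
    wavelet = em_wavelet(m, T = p$T, n_scales = as.integer(p$n_scales)),
    anisotropic_diffusion = em_diffusion(m, eta = p$eta,
      n_iter = as.integer(p$n_iter), kappa = p$kappa,
      variant = if (p$variant >= 2) "rational" else "exponential"),
    bilateral = em_bilateral(m, sigma_sp = p$sigma_sp, sigma_int = p$sigma_int),
    tikhonov = em_tikhonov(m, lam = p$lambda, sigma_psf = p$sigma_psf,
                           n_iter = as.integer(p$n_iter)),
    tv = em_tv(m, lam = p$lambda, n_iter = as.integer(p$n_iter), eps = p$eps),
    blsgsm = em_blsgsm(m, sigma_n = p$sigma_n, J = as.integer(p$J),
                       K_orient = as.integer(p$K_orient)),
    nlm = em_nlm(m, h = p$h, B = as.integer(p$B), W = as.integer(p$W)),
    nlm_deconv = em_nlm_deconv(m, h = p$h, B = as.integer(p$B),
                               W = as.integer(p$W), lam = p$lambda,
                               sigma_psf = p$sigma_psf,
                               n_iter = as.integer(p$n_iter))$estimate)
}

#' Spatial influence radius of an algorithm
#'
#' The half-width of the region around a pixel that can affect its restored
#' value: used to validate ROI preview margins. Iterative/global methods
#' (wavelet, Tikhonov, TV, BLS-GSM, NLM deconvolution) return \code{Inf};
#' their previews are border-approximate unless the ROI covers the slice.
#'
#' @param spec an \code{algorithm_spec}.
#' @return radius in pixels (possibly \code{Inf}).
#' @export
influence_radius <- function(spec) {
  p <- spec$params
  switch(spec$algorithm,
    gaussian = 3,
    bilateral = 7,
    anisotropic_diffusion = p$n_iter,
    nlm = p$B + p$W,
    Inf)
}

#' Region-of-interest specification
#'
#' A rectangle on one slice, 1-based inclusive bounds (rows \code{y0:y1},
#' columns \code{x0:x1}), with a context margin used for preview.
#'
#' @param z slice index (1-based).
#' @param y0,y1,x0,x1 inclusive rectangle bounds.
#' @param margin context padding in pixels (>= 0).
#' @return a \code{roi_spec} object.
#' @export
roi_spec <- function(z, y0, y1, x0, x1, margin = 0L) {
  if (y0 > y1 || x0 > x1 || y0 < 1 || x0 < 1) stop("invalid ROI rectangle")
  if (margin < 0) stop("margin must be >= 0")
  structure(list(z = as.integer(z), y0 = as.integer(y0), y1 = as.integer(y1),
                 x0 = as.integer(x0), x1 = as.integer(x1),
                 margin = as.integer(margin)),
            class = "roi_spec")
}

#' Preview a restoration on a region of interest
#'
#' Denoises the margin-expanded rectangle (clipped to the slice) and
#' returns the central crop. When the margin reaches the algorithm's
#' influence radius the preview is identical to the same crop of a
#' full-slice run; otherwise a warning notes that border pixels may
#' differ.
#'
#' @param volume an \code{em_volume}.
#' @param roi a \code{\link{roi_spec}}.
#' @param spec an \code{\link{algorithm_spec}}.
#' @return matrix of the restored ROI (same size as the rectangle).
#' @export
preview_roi <- function(volume, roi, spec) {
  stopifnot(inherits(roi, "roi_spec"))
  s <- get_slice(volume, roi$z)
  if (roi$y1 > nrow(s) || roi$x1 > ncol(s)) stop("ROI outside slice bounds")
  covers_slice <- roi$y0 == 1 && roi$x0 == 1 &&
    roi$y1 == nrow(s) && roi$x1 == ncol(s)
  if (roi$margin < influence_radius(spec) && !covers_slice)
    warning("margin smaller than the algorithm's influence radius: ",
            "preview borders may differ from a full-slice run")
  ey0 <- max(1L, roi$y0 - roi$margin); ey1 <- min(nrow(s), roi$y1 + roi$margin)
  ex0 <- max(1L, roi$x0 - roi$margin); ex1 <- min(ncol(s), roi$x1 + roi$margin)
  out <- run_algorithm(s[ey0:ey1, ex0:ex1, drop = FALSE], spec)
  out[(roi$y0 - ey0 + 1):(roi$y1 - ey0 + 1),
      (roi$x0 - ex0 + 1):(roi$x1 - ex0 + 1), drop = FALSE]
}

#' Reproducibility record for a restoration run
#'
#' Captures everything needed to re-run a restoration bit-identically:
#' the algorithm spec, the noise/blur estimates at run time, the slice
#' range, a checksum of the input data and a timestamp.
#'
#' @param spec an \code{algorithm_spec}.
#' @param sigma_hat,blur optional estimates recorded for provenance.
#' @param slices integer vector of processed slice indices (1-based).
#' @param input_checksum md5 of the input volume data.
#' @param timestamp ISO-8601 string.
#' @return a \code{run_record} object.
#' @export
run_record <- function(spec, sigma_hat = NA_real_, blur = NA_real_,
                       slices = integer(0), input_checksum = "",
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(inherits(spec, "algorithm_spec"))
  structure(list(spec = unclass(spec), sigma_hat = sigma_hat, blur = blur,
                 slices = as.integer(slices), input_checksum = input_checksum,
                 timestamp = timestamp),
            class = "run_record")
}

#' @rdname run_record
#' @param x object to test / print
#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s on slices [%s], input md5 %s\n",
              x$spec$algorithm, paste(range(x$slices), collapse = "-"),
              substr(x$input_checksum, 1, 8)))
  invisible(x)
}

volume_checksum <- function(volume) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(writeBin(as.numeric(as_volume_data(volume)), raw(), size = 8,
                    endian = "little"), f)
  unname(tools::md5sum(f))
}

#' Apply an algorithm to a stack, slice by slice
#'
#' Restores each selected slice independently (2D processing); slices
#' outside \code{slice_range} are copied verbatim. The input volume is
#' never mutated. A per-slice failure aborts with the failing index.
#'
#' @param volume an \code{em_volume}.
#' @param spec an \code{\link{algorithm_spec}}.
#' @param slice_range integer vector of slice indices (1-based), default
#'   all slices.
#' @param verbose print per-slice progress to stderr.
#' @return list with \code{volume} (restored \code{em_volume}) and
#'   \code{record} (a \code{\link{run_record}}).
#' @export
apply_to_stack <- function(volume, spec, slice_range = NULL, verbose = FALSE) {
  stopifnot(inherits(volume, "em_volume"), inherits(spec, "algorithm_spec"))
  nz <- dim(volume$data)[3]
  if (is.null(slice_range)) slice_range <- seq_len(nz)
  if (any(slice_range < 1 | slice_range > nz)) stop("slice_range out of bounds")
  out <- volume$data
  for (z in slice_range) {
    if (verbose) message(sprintf("slice %d / %d", z, nz))
    res <- tryCatch(run_algorithm(volume$data[, , z], spec),
                    error = function(e)
                      stop(sprintf("slice %d failed: %s", z, conditionMessage(e))))
    out[, , z] <- res
  }
  rec <- run_record(spec, slices = slice_range,
                    input_checksum = volume_checksum(volume))
  md <- volume$metadata
  md$run_record <- unclass(rec)
  list(volume = em_volume(out, voxel_size = volume$voxel_size,
                          source_dtype = volume$source_dtype, metadata = md),
       record = rec)
}

#' Acquisition-time arithmetic for slice-and-view imaging
#'
#' Total wall time in hours for acquiring \code{n_images} frames of
#' \code{pixels_per_image} pixels at \code{dwell_us} microseconds per pixel
#' plus \code{n_slicings} mechanical slicing events of \code{slice_time_s}
#' seconds each:
#' \deqn{t = (n_{img} p\, d \cdot 10^{-6} + n_{slice} t_s) / 3600.}
#' Shorter dwell times acquire faster but noisier frames; combined with
#' denoising this trades compute for beam time.
#'
#' @param n_images number of frames.
#' @param pixels_per_image pixels per frame.
#' @param dwell_us beam dwell time per pixel, microseconds.
#' @param slice_time_s seconds per slicing event (default 18).
#' @param n_slicings number of slicing events.
#' @return total time in hours.
#' @export
acquisition_time <- function(n_images, pixels_per_image, dwell_us,
                             slice_time_s = 18, n_slicings = 0) {
  vals <- c(n_images, pixels_per_image, dwell_us, slice_time_s, n_slicings)
  if (any(vals < 0)) stop("all plan quantities must be >= 0")
  (n_images * pixels_per_image * dwell_us * 1e-6 +
     n_slicings * slice_time_s) / 3600
}
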