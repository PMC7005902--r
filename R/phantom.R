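#' EM-like phantom images with known ground truth
#'
#' Three generators emulate structures commonly segmented in volume EM:
#' \itemize{
#'   \item \code{phantom_membranes}: a Voronoi-style cell partition with dark
#'     membranes of configurable width on a bright, weakly textured
#'     background (neuropil-like tissue).
#'   \item \code{phantom_sarcomere}: alternating dark A-bands and bright
#'     I-bands of striated muscle, with smooth band transitions.
#'   \item \code{phantom_filaments}: non-overlapping bright filament
#'     cross-sections (disks) on a dark background, with a known count.
#' }
#' All phantoms are noise- and blur-free; degradation is applied separately
#' through \code{\link{degrade}} so that every restoration algorithm can be
#' scored against exact ground truth.
#'
#' @name phantoms
NULL

#' @rdname phantoms
#' @param shape integer length-2 image shape \code{(ny, nx)}.
#' @param n_cells number of Voronoi cells (>= 2).
#' @param membrane_width membrane thickness in pixels (>= 1).
#' @param levels intensity levels \code{c(membrane, background)}.
#' @param texture_amp amplitude of the smooth background texture.
#' @param seed RNG seed.
#' @return \code{phantom_membranes}: list with \code{image} (an
#'   \code{em_volume}) and \code{mask} (binary matrix, 1 = membrane).
#' @export
phantom_membranes <- function(shape = c(256L, 256L), n_cells = 12L,
                              membrane_width = 5, levels = c(0.25, 0.75),
                              texture_amp = 0.05, seed = 1L) {
  if (n_cells < 2L) stop("n_cells must be >= 2")
  if (membrane_width < 1) stop("membrane_width must be >= 1")
  ny <- shape[1]; nx <- shape[2]
  if (ny * nx < 16 * n_cells) stop("shape too small for the requested n_cells")
  set.seed(seed)
  cy <- stats::runif(n_cells, 1, ny)
  cx <- stats::runif(n_cells, 1, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  d1 <- matrix(Inf, ny, nx); d2 <- matrix(Inf, ny, nx)
  for (k in seq_len(n_cells)) {
    dk <- sqrt((yy - cy[k])^2 + (xx - cx[k])^2)
    closer <- dk < d1
    d2 <- ifelse(closer, d1, pmin(d2, dk))
    d1 <- pmin(d1, dk)
  }
  # (d2 - d1) is ~ twice the distance to the cell boundary
  mask <- (d2 - d1) <= membrane_width
  tex <- matrix(stats::rnorm(ny * nx, 0, 1), ny, nx)
  tex <- conv2_sep_mirror(tex, gaussian_kernel_1d(3))
  tex <- texture_amp * tex / max(stats::sd(tex), 1e-12)
  img <- ifelse(mask, levels[1], levels[2] + tex)
  img <- pmin(pmax(img, 0), 1)
  list(image = em_volume(img, metadata = list(phantom = "membranes", seed = seed)),
       mask = mask + 0)
}

#' @rdname phantoms
#' @param band_period band period in pixels (>= 2), one A+I pair.
#' @param band_contrast intensity difference between I- and A-band (>= 0;
#'   0 gives a constant image).
#' @param duty fraction of the period occupied by the A-band.
#' @param mid mid-gray level around which the two bands sit.
#' @param edge_sigma standard deviation (px) of the smooth band transition.
#' @return \code{phantom_sarcomere}: list with \code{image} and \code{mask}
#'   (integer matrix, 1 = A-band, 2 = I-band).
#' @export
phantom_sarcomere <- function(shape = c(256L, 256L), band_period = 16,
                              band_contrast = 0.4, duty = 0.5, mid = 0.55,
                              edge_sigma = 1) {
  if (band_period < 2) stop("band_period must be >= 2")
  if (band_contrast < 0) stop("band_contrast must be > 0 (or 0 for a flat field)")
  ny <- shape[1]; nx <- shape[2]
  phase <- (seq_len(ny) - 1) %% band_period
  a_band <- phase < duty * band_period        # A = dark
  prof <- ifelse(a_band, mid - band_contrast / 2, mid + band_contrast / 2)
  if (edge_sigma > 0) {
    # smooth the 1D profile periodically so transitions are gradual
    k <- gaussian_kernel_1d(edge_sigma)
    r <- (length(k) - 1) %/% 2
    idx <- ((seq(-r + 1, ny + r) - 1) %% ny) + 1
    prof <- stats::filter(prof[idx], rev(k), sides = 2)[(r + 1):(ny + r)]
  }
  img <- matrix(prof, ny, nx)
  mask <- matrix(ifelse(a_band, 1L, 2L), ny, nx)
  list(image = em_volume(img, metadata = list(phantom = "sarcomere")),
       mask = mask)
}

#' @rdname phantoms
#' @param n_filaments number of disks to place.
#' @param radius disk radius in pixels.
#' @param fg,bg foreground (disk) and background intensity.
#' @param max_tries rejection-sampling retry cap for disk placement.
#' @return \code{phantom_filaments}: list with \code{image}, binary
#'   \code{mask} and \code{true_count}.
#' @export
phantom_filaments <- function(shape = c(256L, 256L), n_filaments = 25L,
                              radius = 6, fg = 0.8, bg = 0.2,
                              seed = 1L, max_tries = 10000L) {
  ny <- shape[1]; nx <- shape[2]
  set.seed(seed)
  centers <- matrix(numeric(0), 0, 2)
  min_d2 <- (2 * radius + 3)^2   # strictly separated, even 8-connected
  tries <- 0L
  while (nrow(centers) < n_filaments) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("filament placement failed after %d tries (placed %d of %d)",
                   max_tries, nrow(centers), n_filaments))
    cand <- c(stats::runif(1, radius + 2, ny - radius - 1),
              stats::runif(1, radius + 2, nx - radius - 1))
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 > min_d2))
      centers <- rbind(centers, cand)
  }
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  mask <- matrix(FALSE, ny, nx)
  if (n_filaments > 0)
    for (k in seq_len(nrow(centers)))
      mask <- mask | ((yy - centers[k, 1])^2 + (xx - centers[k, 2])^2 <= radius^2)
  img <- ifelse(mask, fg, bg)
  if (radius >= 2) img <- conv2_sep_mirror(img, gaussian_kernel_1d(0.8))
  list(image = em_volume(img, metadata = list(phantom = "filaments", seed = seed)),
       mask = mask + 0, true_count = as.integer(n_filaments),
       centers = centers)
}

#' Stack independent phantom slices into a test volume
#'
#' Convenience wrapper producing a z-stack of membrane phantoms with
#' different seeds, for slice-by-slice workflow tests.
#'
#' @param nz number of slices
#' @param ... passed to \code{\link{phantom_membranes}}
#' @param seed base seed; slice k uses \code{seed + k - 1}
#' @return an \code{em_volume} with \code{nz} slices
#' @export
phantom_stack <- function(nz = 3L, shape = c(64L, 64L), seed = 1L, ...) {
  slices <- lapply(seq_len(nz), function(k)
    get_slice(phantom_membranes(shape = shape, seed = seed + k - 1L, ...)$image))
  em_volume(array(unlist(slices), dim = c(shape[1], shape[2], nz)),
            metadata = list(phantom = "membrane_stack", seed = seed))
}
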