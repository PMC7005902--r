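#' Gaussian filtering
#'
#' Linear smoothing by convolution with a normalized Gaussian kernel on a
#' fixed 7x7 window (the window size is fixed; only the kernel standard
#' deviation \code{sigma_g} is tunable). Mirror boundary handling.
#'
#' @param image matrix or \code{em_volume} slice.
#' @param sigma_g Gaussian standard deviation in pixels (> 0).
#' @return filtered matrix.
#' @export
em_gaussian <- function(image, sigma_g) {
  if (!is.numeric(sigma_g) || sigma_g <= 0) stop("sigma_g must be > 0")
  m <- as_slice_matrix(image)
  k <- gaussian_kernel_1d(sigma_g, radius = 3L)   # fixed 7x7 window
  conv2_sep_mirror(m, k, k)
}

as_slice_matrix <- function(image) {
  if (inherits(image, "em_volume")) {
    if (dim(image$data)[3] != 1L)
      stop("expected a single slice; use apply_to_stack() for volumes")
    return(image$data[, , 1])
  }
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 1L)
    return(image[, , 1])
  stop("expected a 2D image")
}

#' Anisotropic (edge-preserving) diffusion
#'
#' Explicit iterations of the nonlinear diffusion equation
#' \eqn{\partial x/\partial t = \nabla\cdot(c(\|\nabla x\|_2)\nabla x)} on a
#' 4-neighbor stencil with per-arm conductances (Perona-Malik scheme). The
#' conductance \eqn{c(s)} is either the exponential
#' \eqn{\exp(-(s/\kappa)^2)} or the rational \eqn{1/(1+(s/\kappa)^2)}
#' variant; both satisfy \eqn{c(0)=1} and decrease with gradient magnitude
#' so that edges diffuse less than flat regions.
#'
#' @param image matrix or single-slice \code{em_volume}.
#' @param eta explicit time step, in \code{(0, 0.25]} for stability.
#' @param n_iter number of iterations (>= 0).
#' @param kappa edge threshold (> 0): gradients below \code{kappa} are
#'   smoothed, gradients above are preserved.
#' @param variant \code{"exponential"} or \code{"rational"}.
#' @return diffused matrix.
#' @export
em_diffusion <- function(image, eta = 0.07, n_iter = 5L, kappa = 0.18,
                         variant = c("exponential", "rational")) {
  variant <- match.arg(variant)
  if (eta <= 0 || eta > 0.25)
    stop("eta outside the explicit-scheme stability range (0, 0.25]")
  if (kappa <= 0) stop("kappa must be > 0")
  if (n_iter < 0) stop("n_iter must be >= 0")
  x <- as_slice_matrix(image)
  ny <- nrow(x); nx <- ncol(x)
  cond <- diffusion_conductance(variant)
  for (it in seq_len(n_iter)) {
    # forward differences toward each of the 4 neighbors (mirror boundary:
    # the out-of-domain difference is 0, i.e. no flux through the border)
    dN <- rbind(x[1, , drop = FALSE] * 0, x[-ny, , drop = FALSE] - x[-1, , drop = FALSE])
    dS <- rbind(x[-1, , drop = FALSE] - x[-ny, , drop = FALSE], x[1, , drop = FALSE] * 0)
    dW <- cbind(x[, 1, drop = FALSE] * 0, x[, -nx, drop = FALSE] - x[, -1, drop = FALSE])
    dE <- cbind(x[, -1, drop = FALSE] - x[, -nx, drop = FALSE], x[, 1, drop = FALSE] * 0)
    x <- x + eta * (cond(abs(dN), kappa) * dN + cond(abs(dS), kappa) * dS +
                    cond(abs(dW), kappa) * dW + cond(abs(dE), kappa) * dE)
  }
  x
}

#' Diffusion conductance functions
#'
#' Returns the conductance \eqn{c(s)} used by \code{\link{em_diffusion}}:
#' exponential \eqn{\exp(-(s/\kappa)^2)} or rational
#' \eqn{1/(1+(s/\kappa)^2)}. At \eqn{s = \kappa} they evaluate to
#' \eqn{e^{-1}} and \eqn{1/2} respectively.
#'
#' @param variant \code{"exponential"} or \code{"rational"}.
#' @return a function \code{c(s, kappa)}.
#' @export
diffusion_conductance <- function(variant = c("exponential", "rational")) {
  variant <- match.arg(variant)
  if (variant == "exponential") function(s, kappa) exp(-(s / kappa)^2)
  else function(s, kappa) 1 / (1 + (s / kappa)^2)
}

#' Bilateral filtering
#'
#' Edge-preserving weighted mean over a fixed 15x15 window: the weight of
#' neighbor j for reference pixel i is the product of a spatial Gaussian
#' \eqn{f_{sp}(\|p_i-p_j\|_2)} with standard deviation \code{sigma_sp} and
#' an intensity ("range") Gaussian \eqn{f_{int}(|y_i-y_j|)} with standard
#' deviation \code{sigma_int}, normalized to unit sum per pixel so that
#' constant images are preserved. Mirror boundary.
#'
#' @param image matrix or single-slice \code{em_volume}.
#' @param sigma_sp spatial kernel standard deviation in pixels (> 0).
#' @param sigma_int intensity kernel standard deviation on the \code{[0,1]}
#'   scale (> 0).
#' @return filtered matrix.
#' @export
em_bilateral <- function(image, sigma_sp = 3, sigma_int = 0.1) {
  if (sigma_sp <= 0 || sigma_int <= 0) stop("sigma_sp and sigma_int must be > 0")
  m <- as_slice_matrix(image)
  r <- 7L                                   # fixed 15x15 window
  p <- mirror_pad(m, r, r)
  ny <- nrow(m); nx <- ncol(m)
  num <- matrix(0, ny, nx); den <- matrix(0, ny, nx)
  for (dy in -r:r) for (dx in -r:r) {
    shifted <- p[(r + 1 + dy):(r + ny + dy), (r + 1 + dx):(r + nx + dx), drop = FALSE]
    w_sp <- exp(-(dy^2 + dx^2) / (2 * sigma_sp^2))
    w <- w_sp * exp(-(m - shifted)^2 / (2 * sigma_int^2))
    num <- num + w * shifted
    den <- den + w
  }
  num / den
}
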