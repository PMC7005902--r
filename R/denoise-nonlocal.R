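# Nonlocal means denoising and deconvolution.
#
# Patch-similarity weights w_ij = exp(-0.5 ||y_Ni - y_Nj||^2 / h) over a
# (2W+1)^2 search window, with (2B+1)^2 patches; the patch distance is the
# raw squared L2 without per-pixel normalization, and h lives on the [0,1]
# intensity scale (so printed damping values reproduce behavior only at the
# stated B). Borders use mirror-padded patches: both the neighbor values and
# the patch contents come from one symmetric extension of the image.

validate_nlm <- function(h, B, W) {
  if (h <= 0) stop("h must be > 0")
  if (B < 1) stop("half patch size B must be >= 1")
  if (W < B) stop("half search window W must be >= B")
}

# per-offset patch squared distances; returns function of offset (dy,dx)
# shared by the weight computation in denoising and deconvolution
nlm_offset_machinery <- function(m, B, W) {
  ny <- nrow(m); nx <- ncol(m)
  R <- W + 2L * B
  P <- mirror_pad(m, R)                          # one consistent extension
  g <- W + B
  # P shifted by (dy,dx) and trimmed by g on each side: size (ny+2B, nx+2B)
  trim <- function(dy, dx)
    P[(1L + g + dy):(nrow(P) - g + dy), (1L + g + dx):(ncol(P) - g + dx), drop = FALSE]
  T0 <- trim(0L, 0L)
  box <- rep(1, 2L * B + 1L)
  core_r <- (B + 1L):(B + ny)                    # in trimmed coordinates
  core_c <- (B + 1L):(B + nx)
  list(
    dist2 = function(dy, dx) {                   # D(i) = ||y_Ni - y_N(i+d)||^2
      E <- (T0 - trim(dy, dx))^2
      S <- stats::filter(E, box, sides = 2)
      S <- t(stats::filter(t(S), box, sides = 2))
      matrix(S[core_r, core_c], ny, nx)
    },
    value = function(dy, dx)                     # y at the neighbor centers
      P[(R + 1L + dy):(R + ny + dy), (R + 1L + dx):(R + nx + dx), drop = FALSE]
  )
}

#' Nonlocal means denoising
#'
#' Restores each pixel as the normalized weighted average of all pixels in
#' its \eqn{(2W+1)^2} search window, with weights
#' \eqn{w_{ij} = \exp(-\tfrac12\|y_{N_i}-y_{N_j}\|_2^2 / h)} computed from
#' \eqn{(2B+1)^2} patch differences. The self-weight is always 1.
#'
#' @param image matrix or single-slice \code{em_volume}.
#' @param h similarity damping parameter (> 0) on the \code{[0,1]} scale.
#' @param B half patch (neighborhood) size (>= 1).
#' @param W half search window size (>= B).
#' @return denoised matrix.
#' @export
em_nlm <- function(image, h = 0.23, B = 4L, W = 5L) {
  validate_nlm(h, B, W)
  m <- as_slice_matrix(image)
  if (min(dim(m)) <= 2L * B + 1L) stop("image smaller than one patch (2B+1)")
  mach <- nlm_offset_machinery(m, as.integer(B), as.integer(W))
  num <- matrix(0, nrow(m), ncol(m)); den <- num
  for (dy in -W:W) for (dx in -W:W) {
    w <- exp(-0.5 * mach$dist2(dy, dx) / h)
    num <- num + w * mach$value(dy, dx)
    den <- den + w
  }
  num / den
}

#' Nonlocal means deconvolution
#'
#' Extends nonlocal means to a deconvolution estimator: minimizes
#' \eqn{\|y - Hx\|_2^2 + \lambda\sum_{ij} w_{ij}(x_i - x_j)^2} where the
#' weights are computed once (same form as \code{\link{em_nlm}}) on a
#' pre-denoised pilot image (one nonlocal-means pass over y) and held
#' fixed. The weight graph is restricted to the \eqn{(2W+1)^2} search
#' window, where essentially all nonzero weights live. The quadratic
#' objective is minimized by conjugate gradients (a Krylov descent scheme:
#' the objective is non-increasing across iterations), initialized at y.
#'
#' @inheritParams em_nlm
#' @param lam regularization weight \eqn{\lambda \ge 0}.
#' @param sigma_psf PSF standard deviation (0 = no blur, H = I).
#' @param n_iter iterations (default 20).
#' @param pilot optional pilot image for the weights; default
#'   \code{em_nlm(image, h, B, W)}.
#' @return list with \code{estimate} (matrix) and \code{objective}
#'   (objective value per iteration, starting at the initial point).
#' @export
em_nlm_deconv <- function(image, h = 0.23, B = 4L, W = 5L, lam = 0.05,
                          sigma_psf = 0, n_iter = 20L, pilot = NULL) {
  validate_nlm(h, B, W)
  if (lam < 0) stop("lambda must be >= 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  y <- as_slice_matrix(image)
  ny <- nrow(y); nx <- ncol(y); n <- ny * nx
  if (is.null(pilot)) pilot <- em_nlm(y, h = h, B = B, W = W)
  Kmat <- nlm_weight_graph(pilot, h, B, W)
  # use the periodic form of H so the CG operator is exactly symmetric
  Hf <- if (sigma_psf > 0) {
    k <- gaussian_kernel_1d(sigma_psf)
    fft2(periodic_embed(outer(k, k), ny, nx))
  } else NULL
  applyHp <- function(x) if (is.null(Hf)) x else ifft2_re(fft2(x) * Hf)
  applyHpT <- function(x) if (is.null(Hf)) x else ifft2_re(fft2(x) * Conj(Hf))
  apply_A <- function(x)
    applyHpT(applyHp(x)) + lam * matrix(as.numeric(Kmat %*% as.vector(x)), ny, nx)
  objective <- function(x)
    sum((y - applyHp(x))^2) + lam * sum(as.vector(x) * as.numeric(Kmat %*% as.vector(x)))
  b <- applyHpT(y)
  x <- y
  obj <- objective(x)
  r <- b - apply_A(x)
  p <- r; rs <- sum(r * r)
  for (it in seq_len(n_iter)) {
    if (rs < 1e-30) { obj <- c(obj, objective(x)); next }
    Ap <- apply_A(p)
    denom <- sum(p * Ap)
    if (denom <= 0) { warning("step-size collapse in NLM deconvolution"); break }
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    obj <- c(obj, objective(x))
  }
  list(estimate = x, objective = obj)
}

#' Nonlocal weight graph as a sparse quadratic form
#'
#' Builds the sparse matrix \code{K} such that
#' \eqn{x^T K x = \sum_{i,\delta} w_{i,i+\delta}(x_i - x_{i+\delta})^2}
#' with weights computed on \code{pilot} and out-of-image neighbors mapped
#' back by mirror reflection. Used by \code{\link{em_nlm_deconv}}.
#'
#' @param pilot matrix the patch weights are computed from.
#' @inheritParams em_nlm
#' @return a symmetric sparse \code{Matrix::dgCMatrix}.
#' @export
nlm_weight_graph <- function(pilot, h, B = 4L, W = 5L) {
  m <- as_slice_matrix(pilot)
  ny <- nrow(m); nx <- ncol(m); n <- ny * nx
  mach <- nlm_offset_machinery(m, as.integer(B), as.integer(W))
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  offs <- expand.grid(dy = -W:W, dx = -W:W)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  jj <- vector("list", nrow(offs)); ww <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    w <- exp(-0.5 * mach$dist2(dy, dx) / h)
    jj[[k]] <- (reflect_index(as.vector(xx + dx), nx) - 1L) * ny +
      reflect_index(as.vector(yy + dy), ny)
    ww[[k]] <- as.vector(w)
  }
  Wm <- Matrix::sparseMatrix(i = rep.int(seq_len(n), nrow(offs)),
                             j = unlist(jj), x = unlist(ww), dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(Wm) + Matrix::colSums(Wm)) - Wm - Matrix::t(Wm)
}
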