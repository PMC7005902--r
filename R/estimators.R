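#' Robust noise-level estimation (median absolute deviation)
#'
#' Two variants are provided. \code{mad_raw} is the literal estimator
#' \eqn{\hat\sigma = med(|y - med(y)|)} applied to raw intensities: it is a
#' robust scale of the whole image and conflates texture with noise, so it
#' is reported for diagnostics. \code{mad_wavelet} applies the MAD to the
#' finest diagonal wavelet detail coefficients and divides by 0.6745 (the
#' median of |N(0,1)|), which makes it a consistent estimator of the
#' additive Gaussian noise standard deviation on structured images; the
#' automatic parameter initialization uses this variant.
#'
#' @param image matrix, 3D array or \code{em_volume} (first slice used for a
#'   volume is not assumed: the whole array is pooled).
#' @param method \code{"mad_wavelet"} (default, calibrated) or
#'   \code{"mad_raw"} (literal).
#' @return list with \code{sigma_hat} and \code{method}.
#' @export
estimate_noise_mad <- function(image, method = c("mad_wavelet", "mad_raw")) {
  method <- match.arg(method)
  a <- as_volume_data(image)
  if (length(a) < 2) stop("need at least 2 pixels to estimate noise")
  sigma_hat <- if (method == "mad_raw") {
    stats::median(abs(a - stats::median(a)))
  } else {
    d <- unlist(lapply(seq_len(dim(a)[3]), function(z) {
      m <- a[, , z]
      ny <- nrow(m) - nrow(m) %% 2L
      nx <- ncol(m) - ncol(m) %% 2L
      if (ny < 2 || nx < 2) return(numeric(0))
      io <- seq(1L, ny, by = 2L); ie <- io + 1L
      jo <- seq(1L, nx, by = 2L); je <- jo + 1L
      # decimated Haar diagonal detail: std sigma for i.i.d. noise
      (m[io, jo, drop = FALSE] - m[ie, jo, drop = FALSE] -
         m[io, je, drop = FALSE] + m[ie, je, drop = FALSE]) / 2
    }))
    if (!length(d)) stop("image too small for wavelet MAD")
    stats::median(abs(d)) / 0.6745
  }
  list(sigma_hat = as.numeric(sigma_hat), method = method)
}

#' Blur-level estimation from smoothing-induced variation loss
#'
#' Quantifies blur in \code{[0, 1]} (0 = sharp, 1 = fully blurred) by
#' comparing pixel variation before and after 1D moving-average smoothing.
#' With \eqn{y' = S_x y} (horizontal moving average of length
#' \code{smoothing_len}) and first-order forward differences \eqn{D_x}, the
#' per-pixel variation retained by smoothing is
#' \eqn{v_x = \max(0, |D_x y| - |D_x y'|)} and the horizontal blur level is
#' \eqn{b_x = (\sum|D_x y| - \sum v_x) / \sum|D_x y|}. A sharp image loses
#' most of its variation under smoothing (\eqn{v_x \approx |D_x y|}, so
#' \eqn{b_x \approx 0}); an already blurred image loses little
#' (\eqn{b_x \approx 1}). The vertical component is symmetric and the final
#' metric is \code{b = max(b_x, b_y)}. Absolute differences are used so the
#' normalization cannot go negative.
#'
#' @param image matrix or \code{em_volume} (single slice).
#' @param smoothing_len odd length of the moving-average window.
#' @return list with \code{b}, \code{b_x}, \code{b_y}, \code{smoothing_len}.
#' @export
estimate_blur <- function(image, smoothing_len = 9L) {
  m <- as_volume_data(image)[, , 1]
  if (smoothing_len < 3L || smoothing_len %% 2L == 0L)
    stop("smoothing_len must be odd and >= 3")
  blur_1d <- function(m) {           # horizontal direction (along x)
    k <- rep(1 / smoothing_len, smoothing_len)
    ms <- conv2_sep_mirror(m, 1, k)
    ady  <- abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
    adys <- abs(ms[, -1, drop = FALSE] - ms[, -ncol(ms), drop = FALSE])
    v <- pmax(0, ady - adys)
    tot <- sum(ady)
    if (tot <= 0) return(NA_real_)
    (tot - sum(v)) / tot
  }
  b_x <- blur_1d(m)
  b_y <- blur_1d(t(m))
  if (is.na(b_x) && is.na(b_y))
    stop("constant image: blur level is undefined (zero total variation)")
  b_x <- if (is.na(b_x)) 0 else b_x
  b_y <- if (is.na(b_y)) 0 else b_y
  list(b = max(b_x, b_y), b_x = b_x, b_y = b_y,
       smoothing_len = as.integer(smoothing_len))
}
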