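# Evaluation utilities: PSNR, Dice overlap, intensity thresholding,
# connected-component counting (with optional watershed splitting of
# touching objects) and Fourier high-pass detail maps.

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(1 / MSE)} for images on the unit intensity scale.
#' Identical inputs (MSE = 0) return the sentinel cap of 300 dB.
#'
#' @param estimate,truth same-shape numeric arrays; \code{truth} in [0, 1].
#' @return PSNR in dB.
#' @export
psnr <- function(estimate, truth) {
  a <- as_volume_data(estimate); b <- as_volume_data(truth)
  if (!identical(dim(a), dim(b))) stop("shape mismatch in psnr()")
  mse <- mean((a - b)^2)
  if (mse <= 1e-30) return(300)
  min(10 * log10(1 / mse), 300)
}

#' Dice overlap coefficient
#'
#' \eqn{D = 2|P \cap S| / (|P| + |S|)} between two binary masks; symmetric,
#' in \code{[0, 1]}, defined as 1 when both masks are empty.
#'
#' @param P,S binary masks (0/1 or logical), same shape.
#' @return Dice coefficient.
#' @export
dice <- function(P, S) {
  if (!identical(dim(P), dim(S))) stop("shape mismatch in dice()")
  if (!all(P %in% c(0, 1)) || !all(S %in% c(0, 1)))
    stop("dice() requires binary masks")
  p <- as.logical(P); s <- as.logical(S)
  denom <- sum(p) + sum(s)
  if (denom == 0) return(1)
  2 * sum(p & s) / denom
}

#' Intensity-threshold segmentation
#'
#' Binary mask of pixels with \code{lo <= intensity <= hi} (both ends
#' inclusive, matching closed threshold ranges).
#'
#' @param image matrix or \code{em_volume}.
#' @param lo,hi threshold bounds, \code{lo <= hi}.
#' @return 0/1 mask with the shape of the input.
#' @export
threshold_segment <- function(image, lo, hi) {
  if (lo > hi) stop("lo must be <= hi")
  a <- if (inherits(image, "em_volume")) image$data else image
  (a >= lo & a <= hi) + 0
}

# 8-connected labeling by iterative minimum-label propagation
label_components <- function(mask) {
  m <- mask != 0
  ny <- nrow(m); nx <- ncol(m)
  lab <- matrix(Inf, ny, nx)
  lab[m] <- which(m)
  shift <- function(M, dy, dx, fill = Inf) {
    out <- matrix(fill, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- M[ys - dy, xs - dx, drop = FALSE]
    out
  }
  repeat {
    new <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      new <- pmin(new, shift(lab, dy, dx))
    }
    new[!m] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, ny, nx)
  if (any(m)) {
    ids <- sort(unique(lab[m]))
    out[m] <- match(lab[m], ids)
  }
  out
}

# exact squared Euclidean distance transform (two-pass 1D lower envelope)
edt_squared <- function(mask) {
  m <- mask != 0
  INF <- 1e15
  dt1d <- function(f) {
    n <- length(f)
    if (n == 1) return(f)
    v <- integer(n); zz <- numeric(n + 1)
    d <- numeric(n)
    k <- 1L; v[1] <- 1L; zz[1] <- -INF; zz[2] <- INF
    for (q in 2:n) {
      repeat {
        s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
        if (s <= zz[k]) { k <- k - 1L } else break
      }
      k <- k + 1L
      v[k] <- q; zz[k] <- s; zz[k + 1] <- INF
    }
    k <- 1L
    for (q in 1:n) {
      while (zz[k + 1] < q) k <- k + 1L
      d[q] <- (q - v[k])^2 + f[v[k]]
    }
    d
  }
  g <- ifelse(m, INF, 0)
  g <- apply(g, 2, dt1d)              # along y
  t(apply(g, 1, dt1d))                # along x
}

# marker-based watershed on the negated distance transform: seeds are the
# 3x3 local maxima of the EDT (plateaus merged), flooding in decreasing
# distance order
watershed_split <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(matrix(0L, nrow(mask), ncol(mask)))
  d2 <- edt_squared(m)
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- ifelse(m, d2, -Inf)
  nbmax <- matrix(-Inf, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nbmax <- pmax(nbmax, pad[2:(ny + 1) + dy, 2:(nx + 1) + dx])
  }
  # local EDT maxima (plateaus merged); shallow maxima on 1-px-wide necks
  # and bridges (distance <= sqrt(2)) are suppressed so they cannot seed
  seeds_mask <- m & (d2 >= nbmax) & (d2 > 2)
  if (!any(seeds_mask)) seeds_mask <- m & (d2 >= nbmax)
  seeds <- label_components(seeds_mask)
  lab <- seeds
  ord <- order(d2[m], decreasing = TRUE)
  idx <- which(m)[ord]
  iy <- ((idx - 1L) %% ny) + 1L
  ix <- ((idx - 1L) %/% ny) + 1L
  repeat {
    changed <- FALSE
    for (p in seq_along(idx)) {
      if (lab[idx[p]] != 0L) next
      y <- iy[p]; x <- ix[p]
      for (dy in -1:1) {
        yy <- y + dy
        if (yy < 1 || yy > ny) next
        for (dx in -1:1) {
          xx <- x + dx
          if (xx < 1 || xx > nx) next
          l <- lab[yy, xx]
          if (l != 0L) { lab[idx[p]] <- l; changed <- TRUE; break }
        }
        if (lab[idx[p]] != 0L) break
      }
    }
    if (!changed || !any(lab[m] == 0L)) break
  }
  lab
}

#' Count objects in a binary mask
#'
#' 8-connected component count after removing components smaller than
#' \code{min_size} pixels; with \code{split_touching = TRUE} a
#' distance-transform watershed is applied first so that touching objects
#' are separated (the automated counting workflow: threshold, optional
#' watershed, particle count).
#'
#' @param mask binary matrix.
#' @param min_size minimum component size in pixels.
#' @param split_touching apply watershed splitting before counting?
#' @return list with \code{count} and \code{labels} (integer label matrix).
#' @export
count_components <- function(mask, min_size = 0L, split_touching = FALSE) {
  if (!all(mask %in% c(0, 1))) stop("count_components() requires a binary mask")
  labels <- if (split_touching) watershed_split(mask) else label_components(mask)
  if (min_size > 0 && any(labels > 0)) {
    tab <- table(labels[labels > 0])
    drop <- as.integer(names(tab)[tab < min_size])
    labels[labels %in% drop] <- 0L
  }
  ids <- sort(unique(labels[labels > 0]))
  relab <- matrix(0L, nrow(labels), ncol(labels))
  if (length(ids)) relab[labels > 0] <- match(labels[labels > 0], ids)
  list(count = length(ids), labels = relab)
}

#' Fourier high-pass detail map
#'
#' Zeroes all Fourier coefficients with radial frequency below
#' \code{cutoff_frac} of the Nyquist frequency and inverse-transforms,
#' yielding the edge/detail map used to compare the sharpness of
#' restorations: more residual structure in the map means more
#' high-frequency content survived.
#'
#' @param image matrix or single-slice \code{em_volume}.
#' @param cutoff_frac radial cutoff as a fraction of Nyquist, in (0, 1).
#' @return real-valued detail map, same shape.
#' @export
highpass_detail <- function(image, cutoff_frac = 0.25) {
  if (cutoff_frac <= 0 || cutoff_frac >= 1) stop("cutoff_frac must be in (0,1)")
  m <- as_slice_matrix(image)
  ny <- nrow(m); nx <- ncol(m)
  fy <- (seq_len(ny) - 1) / ny; fy <- ifelse(fy >= 0.5, fy - 1, fy) * 2  # Nyquist units
  fx <- (seq_len(nx) - 1) / nx; fx <- ifelse(fx >= 0.5, fx - 1, fx) * 2
  r <- sqrt(outer(fy^2, fx^2, `+`))
  Fm <- fft2(m)
  Fm[r < cutoff_frac] <- 0
  ifft2_re(Fm)
}
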