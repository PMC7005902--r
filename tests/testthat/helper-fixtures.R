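# Shared fixtures and small independent oracles used across test files.
# Everything is generated in code; no binary fixtures.

fix_membranes <- function(shape = c(64L, 64L), seed = 1L, ...)
  phantom_membranes(shape = shape, seed = seed, ...)

fix_noisy <- function(clean_vol, sigma, seed = 7L)
  get_slice(degrade(clean_vol, degradation_model(0, sigma, seed = seed)))

# brute-force 2D convolution with symmetric (mirror) padding
oracle_conv2 <- function(m, kernel2d) {
  r <- (nrow(kernel2d) - 1) %/% 2
  refl <- function(i, n) { p <- (i - 1) %% (2 * n); ifelse(p < n, p + 1, 2 * n - p) }
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + kernel2d[a + r + 1, b + r + 1] *
        m[refl(i + a, nrow(m)), refl(j + b, ncol(m))]
    out[i, j] <- acc
  }
  out
}

# brute-force bilateral filter, fixed 15x15 window, mirror padding
oracle_bilateral <- function(m, sigma_sp, sigma_int) {
  r <- 7L
  refl <- function(i, n) { p <- (i - 1) %% (2 * n); ifelse(p < n, p + 1, 2 * n - p) }
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    num <- 0; den <- 0
    for (a in -r:r) for (b in -r:r) {
      v <- m[refl(i + a, nrow(m)), refl(j + b, ncol(m))]
      w <- exp(-(a^2 + b^2) / (2 * sigma_sp^2)) *
        exp(-(m[i, j] - v)^2 / (2 * sigma_int^2))
      num <- num + w * v; den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# brute-force nonlocal means; same mirror-extension contract as the package
# (one symmetric pad of W+2B), but implemented by direct double loops
oracle_nlm <- function(m, h, B, W) {
  R <- W + 2L * B
  refl <- function(i, n) { p <- (i - 1) %% (2 * n); ifelse(p < n, p + 1, 2 * n - p) }
  P <- m[refl(seq_len(nrow(m) + 2 * R) - R, nrow(m)),
         refl(seq_len(ncol(m) + 2 * R) - R, ncol(m))]
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    num <- 0; den <- 0
    for (dy in -W:W) for (dx in -W:W) {
      D <- 0
      for (py in -B:B) for (px in -B:B)
        D <- D + (P[i + R + py, j + R + px] -
                    P[i + R + dy + py, j + R + dx + px])^2
      w <- exp(-0.5 * D / h)
      num <- num + w * P[i + R + dy, j + R + dx]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

expect_psnr_gain <- function(estimate, noisy, truth, min_gain) {
  gain <- psnr(estimate, truth) - psnr(noisy, truth)
  expect_gte(gain, min_gain)
  invisible(gain)
}
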