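# Nonlocal means denoising and deconvolution.

test_that("nonlocal means equals the brute-force double-loop oracle", {
  set.seed(41); m <- matrix(runif(12 * 12), 12, 12)
  expect_equal(em_nlm(m, h = 0.5, B = 1L, W = 2L),
               oracle_nlm(m, 0.5, 1L, 2L), tolerance = 1e-12)
})

test_that("nonlocal means fixed points and limits", {
  expect_equal(em_nlm(matrix(0.4, 16, 16), h = 0.2, B = 2L, W = 3L),
               matrix(0.4, 16, 16), tolerance = 1e-12)
  # h -> infinity: unweighted mean of the mirror-extended search window
  set.seed(42); m <- matrix(runif(12 * 12), 12, 12)
  R <- 2L + 2L * 1L
  refl <- function(i, n) { p <- (i - 1) %% (2 * n); ifelse(p < n, p + 1, 2 * n - p) }
  P <- m[refl(seq_len(12 + 2 * R) - R, 12), refl(seq_len(12 + 2 * R) - R, 12)]
  un <- m
  for (i in 1:12) for (j in 1:12)
    un[i, j] <- mean(P[i + R + (-2:2), j + R + (-2:2)])
  expect_equal(em_nlm(m, h = 1e9, B = 1L, W = 2L), un, tolerance = 1e-8)
  expect_error(em_nlm(m, h = 0, B = 1L, W = 2L), "h must")
  expect_error(em_nlm(m, h = 0.2, B = 3L, W = 2L), "W")
})

test_that("nonlocal means output stays within the local search-window range", {
  set.seed(43); m <- matrix(runif(20 * 20), 20, 20)
  out <- em_nlm(m, h = 0.1, B = 2L, W = 4L)
  expect_gte(min(out), min(m) - 1e-12)
  expect_lte(max(out), max(m) + 1e-12)
})

test_that("decreasing h strictly decreases every off-center weight", {
  set.seed(44); m <- matrix(runif(10 * 10), 10, 10)
  g <- emrestore:::nlm_offset_machinery(m, 1L, 2L)
  D <- g$dist2(1L, 0L)
  w_small <- exp(-0.5 * D / 0.05)
  w_large <- exp(-0.5 * D / 0.5)
  expect_true(all(w_small < w_large | D == 0))
})

test_that("NLM deconvolution: identity, monotone objective, dense-solve oracle", {
  set.seed(45); s8 <- matrix(runif(64), 8, 8)
  idres <- em_nlm_deconv(s8, h = 0.4, B = 1L, W = 2L, lam = 0, sigma_psf = 0,
                         n_iter = 10L)
  expect_lt(max(abs(idres$estimate - s8)), 1e-8)

  lam <- 0.3
  res <- em_nlm_deconv(s8, h = 0.4, B = 1L, W = 2L, lam = lam, sigma_psf = 0,
                       n_iter = 80L)
  expect_true(all(diff(res$objective) <= 1e-9))

  # dense linear-algebra oracle on the same weight graph contract
  pilot <- em_nlm(s8, 0.4, 1L, 2L)
  refl <- function(i, n) { p <- (i - 1) %% (2 * n); ifelse(p < n, p + 1, 2 * n - p) }
  R <- 2L + 2L; P <- pilot[refl(seq_len(8 + 2 * R) - R, 8),
                           refl(seq_len(8 + 2 * R) - R, 8)]
  K <- matrix(0, 64, 64)
  for (i in 1:8) for (j in 1:8) for (dy in -2:2) for (dx in -2:2) {
    if (dy == 0 && dx == 0) next
    D <- 0
    for (py in -1:1) for (px in -1:1)
      D <- D + (P[i + R + py, j + R + px] - P[i + R + dy + py, j + R + dx + px])^2
    w <- exp(-0.5 * D / 0.4)
    a <- (j - 1) * 8 + i
    b <- (refl(j + dx, 8) - 1) * 8 + refl(i + dy, 8)
    K[a, a] <- K[a, a] + w; K[b, b] <- K[b, b] + w
    K[a, b] <- K[a, b] - w; K[b, a] <- K[b, a] - w
  }
  oracle <- solve(diag(64) + lam * K, as.vector(s8))
  expect_lt(max(abs(as.vector(res$estimate) - oracle)), 1e-6)
})

test_that("a blurred noisy phantom keeps the deconvolution objective monotone", {
  ph <- fix_membranes(c(32L, 32L), n_cells = 4L, seed = 46L)
  y <- get_slice(degrade(ph$image, degradation_model(1, 0.05, seed = 46L)))
  res <- em_nlm_deconv(y, h = 0.23, B = 2L, W = 3L, lam = 0.05,
                       sigma_psf = 1, n_iter = 20L)
  expect_true(all(diff(res$objective) <= 1e-9))
})
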