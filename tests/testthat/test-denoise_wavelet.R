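# Dual-tree complex wavelet shrinkage and BLS-GSM.

test_that("soft thresholding follows the shrinkage formula", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.1, 0.2), 0)
  set.seed(1); z <- rnorm(50)
  expect_identical(soft_threshold(z, 0), z)
  # complex coefficients: magnitude shrinks, phase is preserved
  zc <- complex(modulus = c(0.5, 0.1), argument = c(1.1, -2))
  out <- soft_threshold(zc, 0.2)
  expect_equal(Mod(out), c(0.3, 0))
  expect_equal(Arg(out[1]), 1.1)
})

test_that("T = 0 wavelet round trip is near-exact; deep scales are rejected", {
  set.seed(2); m <- matrix(runif(64 * 64), 64, 64)
  expect_lt(max(abs(em_wavelet(m, T = 0, n_scales = 6L) - m)), 1e-6)
  expect_error(em_wavelet(matrix(0.1, 16, 16), T = 0.1, n_scales = 6L),
               "too deep")
})

test_that("a threshold above every detail magnitude leaves only the approximation", {
  set.seed(3); m <- matrix(runif(32 * 32), 32, 32)
  dec <- dtcwt_forward(m, 3L)
  # oracle: zero all details in all four trees, invert
  for (tr in names(dec$trees)) for (s in 1:3)
    for (b in c("LH", "HL", "HH"))
      dec$trees[[tr]]$details[[s]][[b]][] <- 0
  approx_only <- dtcwt_inverse(dec)
  expect_equal(em_wavelet(m, T = 1e3, n_scales = 3L), approx_only,
               tolerance = 1e-10)
})

test_that("wavelet shrinkage is non-expansive on detail energy and denoises", {
  ph <- phantom_sarcomere(c(128L, 128L))
  x <- get_slice(ph$image)
  y <- fix_noisy(ph$image, 0.1, seed = 17L)
  detail_energy <- function(m, n_scales = 4L) {
    dec <- dtcwt_forward(m, n_scales)
    sum(unlist(lapply(dec$trees, function(tr)
      lapply(tr$details, function(lv) lapply(lv, function(b) sum(b^2))))))
  }
  xhat <- em_wavelet(y, T = 0.12, n_scales = 4L)
  expect_lte(detail_energy(xhat), detail_energy(y))
  expect_gt(psnr(xhat, x), psnr(y, x))
})

test_that("GSM Wiener estimate matches its closed forms", {
  expect_equal(wiener_gsm(2, 1, matrix(1), matrix(1)), 1)
  set.seed(4)
  C <- crossprod(matrix(rnorm(9), 3, 3)); w <- rnorm(3)
  expect_equal(wiener_gsm(w, 1, C, 0 * C), w)            # noise-free limit
  expect_equal(wiener_gsm(w, 0, C, diag(3)), rep(0, 3))  # z = 0
  expect_error(wiener_gsm(w, 0, C, 0 * C), "singular")
  # linear in w with spectral norm <= 1
  w2 <- rnorm(3)
  lhs <- wiener_gsm(w + 2 * w2, 0.7, C, diag(3))
  rhs <- wiener_gsm(w, 0.7, C, diag(3)) + 2 * wiener_gsm(w2, 0.7, C, diag(3))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  G <- 0.7 * C %*% solve(0.7 * C + diag(3))
  expect_lte(max(abs(eigen(G)$values)), 1 + 1e-12)
})

test_that("steerable pyramid is a self-inverting tight frame", {
  set.seed(5); m <- matrix(runif(48 * 48), 48, 48)
  dec <- steer_decompose(m, J = 3L, K_orient = 8L)
  expect_lt(max(abs(steer_reconstruct(dec) - m)), 1e-12)
  expect_length(dec$subbands, 3 * 8 + 2)
})

test_that("BLS-GSM is deterministic, near-identity for vanishing noise, and effective", {
  ph <- fix_membranes(c(64L, 64L), seed = 6L)
  x <- get_slice(ph$image)
  expect_lt(max(abs(em_blsgsm(x, sigma_n = 1e-6) - x)), 1e-3)
  y <- fix_noisy(ph$image, 0.1, seed = 23L)
  d1 <- em_blsgsm(y, sigma_n = 0.1)
  d2 <- em_blsgsm(y, sigma_n = 0.1)
  expect_identical(d1, d2)
  expect_gt(psnr(d1, x), psnr(y, x) + 2)
})
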