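# Gaussian, anisotropic diffusion and bilateral filters.

test_that("gaussian filter matches the brute-force convolution oracle", {
  set.seed(12); m <- matrix(runif(32 * 32), 32, 32)
  k <- exp(-(-3:3)^2 / (2 * 1.1^2)); k <- k / sum(k)
  expect_equal(em_gaussian(m, 1.1), oracle_conv2(m, outer(k, k)),
               tolerance = 1e-10)
  # fixed points: constant image, impulse reproduces the 7x7 kernel
  expect_equal(em_gaussian(matrix(0.7, 16, 16), 2), matrix(0.7, 16, 16),
               tolerance = 1e-12)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  expect_equal(em_gaussian(imp, 1.1)[5:11, 5:11], outer(k, k),
               tolerance = 1e-12)
  expect_error(em_gaussian(m, 0), "sigma_g")
})

test_that("diffusion conductances take their analytic values at s = kappa", {
  expect_equal(diffusion_conductance("exponential")(0.18, 0.18), exp(-1))
  expect_equal(diffusion_conductance("rational")(0.18, 0.18), 0.5)
})

test_that("diffusion fixed points, stability guard and noise decay", {
  cm <- matrix(0.3, 24, 24)
  expect_equal(em_diffusion(cm, 0.07, 10L, 0.18), cm)             # constant
  set.seed(5); m <- matrix(runif(24 * 24), 24, 24)
  expect_identical(em_diffusion(m, 0.07, 0L, 0.18), m)            # N = 0
  expect_error(em_diffusion(m, 0.3, 5L, 0.18), "stability")
  expect_error(em_diffusion(m, 0.07, 5L, 0), "kappa")
  # variance of a noisy flat region decreases strictly over iterations 1..6
  set.seed(6); flat <- matrix(0.5 + rnorm(48 * 48, 0, 0.05), 48, 48)
  v <- vapply(1:6, function(n)
    var(as.vector(em_diffusion(flat, 0.07, n, 0.18))), numeric(1))
  expect_true(all(diff(c(var(as.vector(flat)), v)) < 0))
})

test_that("diffusion with huge kappa reduces to the linear heat step", {
  set.seed(7); m <- matrix(runif(20 * 20), 20, 20)
  ny <- nrow(m); nx <- ncol(m)
  # independent linear step: x + eta * (4-neighbor Laplacian, Neumann)
  dN <- rbind(0, m[-ny, ] - m[-1, ]); dS <- rbind(m[-1, ] - m[-ny, ], 0)
  dW <- cbind(0, m[, -nx] - m[, -1]); dE <- cbind(m[, -1] - m[, -nx], 0)
  linear <- m + 0.2 * (dN + dS + dW + dE)
  for (variant in c("exponential", "rational"))
    expect_lt(max(abs(em_diffusion(m, 0.2, 1L, 1e8, variant) - linear)), 1e-8)
})

test_that("bilateral filter matches the double-loop oracle and its limits", {
  set.seed(8); m <- matrix(runif(16 * 16), 16, 16)
  expect_equal(em_bilateral(m, 2, 0.15), oracle_bilateral(m, 2, 0.15),
               tolerance = 1e-12)
  expect_equal(em_bilateral(matrix(0.4, 20, 20), 3, 0.1), matrix(0.4, 20, 20),
               tolerance = 1e-12)
  # flat intensity kernel -> plain Gaussian-weighted window mean
  k <- exp(-(-7:7)^2 / (2 * 2^2)); k <- k / sum(k)
  gm <- oracle_conv2(m, outer(k, k))
  expect_equal(em_bilateral(m, 2, 1e6), gm, tolerance = 1e-8)
})

test_that("local filters obey the convex-averaging range bound", {
  set.seed(9); m <- matrix(runif(24 * 24), 24, 24)
  for (out in list(em_gaussian(m, 1.5), em_bilateral(m, 2, 0.1),
                   em_diffusion(m, 0.2, 8L, 0.2))) {
    expect_gte(min(out), min(m) - 1e-12)
    expect_lte(max(out), max(m) + 1e-12)
  }
})
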