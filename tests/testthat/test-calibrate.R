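# Parameter calibration: grid search, polynomial fit, prediction.

test_that("grid search returns the single point or the exhaustive argmin", {
  bench <- list(get_slice(fix_membranes(c(32L, 32L), n_cells = 4L, seed = 1L)$image),
                get_slice(phantom_sarcomere(c(32L, 32L))$image))
  single <- grid_search_optimal("gaussian", bench, 0.1,
                                data.frame(sigma = 1.3), seed = 5L)
  expect_equal(single$theta$sigma, 1.3)

  grid <- data.frame(sigma = c(0.5, 1, 2))
  res <- grid_search_optimal("gaussian", bench, 0.1, grid, seed = 5L)
  # independent exhaustive re-evaluation with the same seeds
  sse <- vapply(grid$sigma, function(sg) {
    tot <- 0
    for (k in seq_along(bench)) {
      y <- get_slice(degrade(em_volume(bench[[k]]),
                             degradation_model(0, 0.1, seed = 5L + k)))
      tot <- tot + sum((em_gaussian(y, sg) - bench[[k]])^2)
    }
    tot
  }, numeric(1))
  expect_equal(res$index, which.min(sse))
  expect_equal(res$sse, sse, tolerance = 1e-10)
})

test_that("constant-truth benchmark prefers the strongest smoothing", {
  bench <- list(matrix(0.5, 32, 32))
  grid <- data.frame(sigma = c(0.5, 1, 2, 2.5))
  res <- grid_search_optimal("gaussian", bench, 0.1, grid, seed = 2L)
  expect_equal(res$theta$sigma, 2.5)
  expect_true(all(diff(res$sse) < 0))   # MSE monotone in smoothing strength
})

test_that("polynomial fits recover exact generating laws", {
  sg <- c(0.05, 0.1, 0.15, 0.2)
  c1 <- fit_polynomial(sg, matrix(2 * sg, 4, 1), q = 1L)
  expect_equal(as.numeric(c1), c(0, 2), tolerance = 1e-10)
  c2 <- fit_polynomial(sg, matrix(sg^2, 4, 1), q = 2L)
  expect_equal(as.numeric(c2), c(0, 0, 1), tolerance = 1e-10)
  expect_error(fit_polynomial(c(0.1, 0.1, 0.1), matrix(1:3, 3, 1), 1L),
               "degenerate")
  # nested least squares: quadratic residual never exceeds linear residual
  set.seed(3); th <- matrix(runif(5), 5, 1); sgr <- seq(0.02, 0.2, length.out = 5)
  rss <- function(qd) {
    cf <- fit_polynomial(sgr, th, qd)
    sum((th - outer(sgr, 0:qd, `^`) %*% cf)^2)
  }
  expect_lte(rss(2L), rss(1L) + 1e-12)
})

test_that("prediction composes the fitted polynomial and clips to the grid", {
  tab <- structure(list(
    algorithm = "gaussian", sigma_grid = c(0.05, 0.1, 0.2),
    theta_grid = matrix(c(0.6, 0.7, 0.9), 3, 1, dimnames = list(NULL, "sigma")),
    coeffs = matrix(c(0, 2), 2, 1, dimnames = list(NULL, "sigma")),
    degree = 1L, K = 2L, param_grid = data.frame(sigma = c(0.1, 3)),
    fixed_params = list(), seed = 1L, provenance = list()),
    class = "calibration_table")
  expect_equal(predict_params(0.1, tab)$sigma, 0.2)
  expect_equal(predict_params(0, tab)$sigma, 0.1)   # intercept 0, clipped to grid
  expect_warning(predict_params(0.9, tab), "extrapolat")
})

test_that("tables round-trip through JSON and are deterministic", {
  bench <- list(get_slice(fix_membranes(c(32L, 32L), n_cells = 4L, seed = 7L)$image))
  grid <- data.frame(sigma = c(0.5, 1, 1.5))
  t1 <- build_calibration_table("gaussian", bench, c(0.05, 0.1, 0.15), grid,
                                seed = 9L)
  t2 <- build_calibration_table("gaussian", bench, c(0.05, 0.1, 0.15), grid,
                                seed = 9L)
  expect_identical(t1$theta_grid, t2$theta_grid)
  f <- tempfile(fileext = ".json")
  save_calibration_table(t1, f)
  t3 <- load_calibration_table(f)
  expect_equal(t3$coeffs, t1$coeffs, tolerance = 1e-12)
  expect_equal(t3$degree, t1$degree)
  expect_s3_class(t3, "calibration_table")
})

test_that("shipped calibration tables exist for every algorithm", {
  algs <- c("gaussian", "wavelet", "anisotropic_diffusion", "bilateral",
            "tikhonov", "tv", "blsgsm", "nlm", "nlm_deconv")
  for (a in algs) {
    p <- system.file("extdata", "calib", paste0(a, ".json"),
                     package = "emrestore")
    expect_true(nzchar(p), label = paste("table for", a))
    th <- auto_params(a, 0.1)
    expect_silent(algorithm_spec(a, th))
  }
})
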