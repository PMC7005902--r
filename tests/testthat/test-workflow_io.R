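# TIFF/PNG I/O, ROI preview, slice-by-slice processing, throughput.

test_that("float32 TIFF round trip is bit-exact and metadata survives", {
  set.seed(51)
  v <- em_volume(array(runif(3 * 32 * 32), c(32, 32, 3)))
  rec <- run_record(algorithm_spec("nlm", list(h = 0.23, B = 4, W = 5)),
                    sigma_hat = 0.07, blur = 0.4, slices = 1:3,
                    input_checksum = "abc")
  f <- tempfile(fileext = ".tif")
  write_volume(v, f, record = rec)
  v1 <- read_volume(f)                 # first cycle quantizes double -> float32
  write_volume(v1, f, record = rec)
  v2 <- read_volume(f)
  expect_identical(v1$data, v2$data)   # bit-identical float32 round trip
  expect_lt(max(abs(v1$data - v$data)), 1e-6)
  rr <- v2$metadata$run_record
  expect_equal(rr$spec$algorithm, "nlm")
  expect_equal(rr$spec$params$h, 0.23)
  expect_equal(rr$sigma_hat, 0.07)
  expect_equal(unlist(rr$slices), 1:3, ignore_attr = TRUE)
})

test_that("16-bit TIFF reads back normalized to [0,1]", {
  m <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  f <- tempfile(fileext = ".tif")
  write_volume(em_volume(m), f, dtype = "uint16")
  v <- read_volume(f)
  expect_equal(v$source_dtype, "uint16")
  expect_equal(v$data[, , 1], round(m * 65535) / 65535, tolerance = 1e-12)
  expect_true(all(v$data >= 0 & v$data <= 1))
})

test_that("PNG export writes a well-formed 8-bit grayscale file", {
  f <- tempfile(fileext = ".png")
  png_export(matrix(seq(0, 1, length.out = 400), 20, 20), f)
  bytes <- readBin(f, "raw", 8)
  expect_identical(bytes, as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  expect_gt(file.size(f), 50)
})

test_that("ROI preview with sufficient margin equals the full-slice crop", {
  ph <- fix_membranes(c(64L, 64L), seed = 52L)
  vol <- degrade(ph$image, degradation_model(0, 0.1, seed = 52L))
  cases <- list(
    list(spec = algorithm_spec("gaussian", list(sigma = 1.5)), margin = 3L),
    list(spec = algorithm_spec("bilateral", list(sigma_sp = 2, sigma_int = 0.1)),
         margin = 7L),
    list(spec = algorithm_spec("nlm", list(h = 0.3, B = 2, W = 3)), margin = 5L))
  for (cs in cases) {
    roi <- roi_spec(1, 20, 40, 15, 45, margin = cs$margin)
    pv <- preview_roi(vol, roi, cs$spec)
    full <- run_algorithm(get_slice(vol, 1), cs$spec)
    expect_lt(max(abs(pv - full[20:40, 15:45])), 1e-10)
  }
  # whole-slice ROI equals the full-slice result even for global algorithms
  roi_all <- roi_spec(1, 1, 64, 1, 64, margin = 0L)
  spec_tv <- algorithm_spec("tv", list(lambda = 0.1, n_iter = 10, eps = 1e-3))
  expect_equal(preview_roi(vol, roi_all, spec_tv),
               run_algorithm(get_slice(vol, 1), spec_tv))
})

test_that("zero-margin previews differ from the crop only near the border", {
  ph <- fix_membranes(c(64L, 64L), seed = 53L)
  spec <- algorithm_spec("gaussian", list(sigma = 1.5))
  roi <- roi_spec(1, 17, 48, 17, 48, margin = 0L)
  expect_warning(pv <- preview_roi(ph$image, roi, spec), "influence radius")
  full <- run_algorithm(get_slice(ph$image, 1), spec)[17:48, 17:48]
  diffmask <- abs(pv - full) > 1e-12
  interior <- diffmask[4:(32 - 3), 4:(32 - 3)]   # beyond the 7x7 half-width
  expect_false(any(interior))
})

test_that("stack processing is slice-independent and never mutates its input", {
  vol <- phantom_stack(nz = 3L, shape = c(32L, 32L), seed = 54L)
  before <- vol$data
  spec <- algorithm_spec("gaussian", list(sigma = 1.2))
  res <- apply_to_stack(vol, spec)
  expect_identical(vol$data, before)
  for (z in 1:3)
    expect_equal(res$volume$data[, , z], em_gaussian(vol$data[, , z], 1.2))
  # partial range copies untouched slices verbatim
  res2 <- apply_to_stack(vol, spec, slice_range = 2L)
  expect_identical(res2$volume$data[, , 1], vol$data[, , 1])
  expect_identical(res2$volume$data[, , 3], vol$data[, , 3])
  expect_equal(res2$volume$data[, , 2], em_gaussian(vol$data[, , 2], 1.2))
  # permuting slice order permutes the output identically
  perm <- vol$data[, , c(3, 1, 2)]
  resp <- apply_to_stack(em_volume(perm), spec)
  expect_equal(resp$volume$data, res$volume$data[, , c(3, 1, 2)])
})

test_that("an embedded run record regenerates the output bit-identically", {
  vol <- phantom_stack(nz = 2L, shape = c(32L, 32L), seed = 55L)
  spec <- algorithm_spec("anisotropic_diffusion",
                         list(eta = 0.07, n_iter = 6, kappa = 0.18, variant = 1))
  res <- apply_to_stack(vol, spec)
  f <- tempfile(fileext = ".tif")
  write_volume(res$volume, f, record = res$record)
  rr <- read_volume(f)$metadata$run_record
  spec2 <- algorithm_spec(rr$spec$algorithm, as.list(unlist(rr$spec$params)))
  res2 <- apply_to_stack(vol, spec2, slice_range = unlist(rr$slices))
  expect_identical(res2$volume$data, res$volume$data)
})

test_that("algorithm specs validate their parameter sets", {
  expect_error(algorithm_spec("gaussian", list(sigma = 1, extra = 2)), "exactly")
  expect_error(algorithm_spec("nlm", list(h = 0.2, B = 4)), "exactly")
  expect_error(algorithm_spec("warp", list()), "unknown algorithm")
  sp <- algorithm_spec("anisotropic_diffusion",
                       list(eta = 0.07, n_iter = 5, kappa = 0.18))
  expect_equal(sp$params$variant, 1)   # exponential conductance by default
})

test_that("acquisition-time arithmetic reproduces the worked dwell-time example", {
  h4 <- acquisition_time(500, 1e8, 4, 18, 499)
  h1 <- acquisition_time(500, 1e8, 1, 18, 499)
  expect_equal(round(h4), 58)
  expect_equal(round(h1), 16)
  expect_equal(round(h4 / h1, 1), 3.5)
  expect_error(acquisition_time(-1, 1e8, 4, 18, 0), ">= 0")
})
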