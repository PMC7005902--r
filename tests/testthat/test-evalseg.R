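# Evaluation: PSNR, Dice, thresholding, component counting, high-pass maps.

test_that("psnr follows the formula with a sentinel cap", {
  expect_equal(psnr(matrix(0.6, 8, 8), matrix(0.5, 8, 8)), 20)
  expect_equal(psnr(matrix(0.3, 8, 8), matrix(0.3, 8, 8)), 300)
  set.seed(61)
  truth <- matrix(0.5, 256, 256)
  noisy <- truth + matrix(rnorm(256^2, 0, 0.1), 256, 256)
  expect_equal(psnr(noisy, truth), 20, tolerance = 0.01)  # 0.2 dB at 256^2
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("dice matches its set formula and is symmetric", {
  m1 <- matrix(0, 10, 10); m1[1:5, ] <- 1
  expect_equal(dice(m1, m1), 1)
  m2 <- matrix(0, 10, 10); m2[6:10, ] <- 1
  expect_equal(dice(m1, m2), 0)
  p <- matrix(0, 10, 20); p[, 1:10] <- 1        # |P| = 100
  s <- matrix(0, 10, 20); s[, 6:15] <- 1        # |S| = 100, overlap 50
  expect_equal(dice(p, s), 0.5)
  expect_equal(dice(p, s), dice(s, p))
  expect_equal(dice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_error(dice(matrix(2, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("threshold segmentation is inclusive at both ends", {
  m <- matrix(c(0.1, 0.3, 0.5, 0.7), 2, 2)
  expect_equal(sum(threshold_segment(m, 0, 1)), 4)
  expect_equal(threshold_segment(m, 0.3, 0.3), (m == 0.3) + 0)
  expect_error(threshold_segment(m, 0.5, 0.1), "lo")
  # two-level sarcomere phantom: the A-band range recovers the A-band label
  ph <- phantom_sarcomere(c(64L, 64L), band_period = 16, band_contrast = 0.4,
                          mid = 0.55, edge_sigma = 0)
  seg <- threshold_segment(get_slice(ph$image), 0.3, 0.4)
  expect_equal(seg, (ph$mask == 1) + 0)
})

test_that("component counting matches construction and splits fused objects", {
  expect_equal(count_components(matrix(0, 16, 16))$count, 0)
  ph <- phantom_filaments(c(96L, 96L), n_filaments = 6L, radius = 5, seed = 62L)
  expect_equal(count_components(ph$mask)$count, 6)
  expect_equal(count_components(ph$mask, split_touching = TRUE)$count, 6)
  # translation invariance away from borders
  shifted <- matrix(0, 96, 96)
  shifted[11:96, 11:96] <- ph$mask[1:86, 1:86]
  expect_equal(count_components(shifted)$count,
               count_components(ph$mask[1:86, 1:86])$count)
  # two disks fused by a 1-px bridge: 1 plain, 2 with watershed splitting
  m <- matrix(0, 40, 60)
  yy <- matrix(1:40, 40, 60); xx <- matrix(1:60, 40, 60, byrow = TRUE)
  m[(yy - 20)^2 + (xx - 20)^2 <= 64] <- 1
  m[(yy - 20)^2 + (xx - 40)^2 <= 64] <- 1
  m[20, 28:32] <- 1
  expect_equal(count_components(m)$count, 1)
  expect_equal(count_components(m, split_touching = TRUE)$count, 2)
  # min_size filtering drops specks
  sp <- matrix(0, 20, 20); sp[2, 2] <- 1; sp[10:14, 10:14] <- 1
  expect_equal(count_components(sp, min_size = 4L)$count, 1)
  expect_error(count_components(matrix(2, 2, 2)), "binary")
})

test_that("high-pass detail map kills low frequencies and conserves energy", {
  expect_equal(max(abs(highpass_detail(matrix(0.7, 32, 32), 0.25))), 0)
  s <- sin(2 * pi * 12 * (0:31) / 32)
  sm <- outer(s, rep(1, 32))
  expect_lt(max(abs(highpass_detail(sm, 0.25) - sm)), 1e-10)
  set.seed(63); e <- matrix(rnorm(32 * 32), 32, 32)
  hp <- highpass_detail(e, 0.3)
  lp <- e - hp
  expect_lt(abs(sum(e^2) - sum(hp^2) - sum(lp^2)), 1e-8)  # orthogonal split
  expect_error(highpass_detail(e, 1.2), "cutoff")
})

test_that("denoising before thresholding does not degrade membrane Dice", {
  ph <- fix_membranes(c(96L, 96L), seed = 64L)
  truth <- ph$mask
  for (sigma in c(0.1, 0.2)) {
    y <- fix_noisy(ph$image, sigma, seed = 65L)
    den <- em_nlm(y, h = 25 * sigma^2, B = 2L, W = 4L)  # h ~ patch size x sigma^2
    d_raw <- dice(threshold_segment(y, -Inf, 0.5), truth)
    d_den <- dice(threshold_segment(den, -Inf, 0.5), truth)
    expect_gte(d_den, d_raw)
  }
})
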