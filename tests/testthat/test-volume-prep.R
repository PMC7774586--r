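test_that("resampling is exact on constants and affine ramps and sizes the grid by FOV", {
  vg <- volume_grid(array(3.5, c(10, 10, 10)), spacing = 1)
  rv <- resample_volume(vg, 0.7)
  expect_true(all(abs(rv$data - 3.5) < 1e-12))
  expect_identical(dim(rv$data), rep(15L, 3))

  # linear ramp along x: trilinear interpolation reproduces it exactly away
  # from the clamped edges
  ramp <- volume_grid(array(rep(1:30, times = 20 * 10), c(30, 20, 10)),
                      spacing = 1)
  rr <- resample_volume(ramp, 0.5)
  expected <- (seq_len(dim(rr$data)[1]) - 0.5) * 0.5 + 0.5
  inner <- 3:(length(expected) - 3)
  expect_lt(max(abs(rr$data[inner, 10, 5] - expected[inner])), 1e-10)

  # 176 samples at 1.0 mm -> 252 samples at 0.7 mm
  big <- volume_grid(array(0, c(4, 4, 176)), spacing = 1)
  expect_identical(dim(resample_volume(big, 0.7)$data)[3], 252L)

  expect_error(resample_volume(vg, -1), "positive")
  expect_error(resample_volume(vg, 0), "positive")
})

test_that("resampling down and back reproduces a smooth volume", {
  # smooth synthetic field (product of cosines)
  d <- c(24, 24, 24)
  vg <- volume_grid(array(0, d), spacing = 1)
  w <- laminargm:::grid_world(vg)
  vg$data <- 2 + cos(w$x / 4) * cos(w$y / 5) * cos(w$z / 6)
  back <- resample_volume(resample_volume(vg, 0.7), 1)
  inner <- 4:21
  a <- vg$data[inner, inner, inner]; b <- back$data[inner, inner, inner]
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.01)
})

test_that("nearest-neighbour resampling preserves the label value set", {
  lab <- volume_grid(array(sample(0:3, 1000, TRUE), c(10, 10, 10)),
                     spacing = 1)
  rl <- resample_volume(lab, 0.6, method = "nearest")
  expect_true(all(rl$data %in% 0:3))
})

test_that("bias-field normalization recovers a quadratic bias within tolerance", {
  bias_c <- c(0, 0, 0, 0, 0.1, 0.1, 0.05, 0, 0, 0)  # ~20% amplitude
  phb <- make_phantom(phantom_spec("shell", noise_sd = 0, bias_coef = bias_c))
  ph0 <- make_phantom(phantom_spec("shell", noise_sd = 0))
  wm <- phb$labels$data == 3L
  expect_gt(diff(range(phb$bias$data[phb$truth$brain_mask])), 0.2)
  nv <- normalize_intensity(phb$intensity, wm)
  gm <- phb$truth$gm_mask
  rel <- abs(nv$data[gm] - ph0$intensity$data[gm]) / ph0$intensity$data[gm]
  expect_lt(max(rel), 0.02)
  # bias-free volume passes through essentially unchanged
  nv0 <- normalize_intensity(ph0$intensity, wm)
  bm <- ph0$truth$brain_mask
  rel0 <- abs(nv0$data[bm] - ph0$intensity$data[bm]) /
    pmax(ph0$intensity$data[bm], 1e-9)
  expect_lt(max(rel0), 0.005)
})

test_that("normalization is idempotent and rejects degenerate inputs", {
  ph <- make_phantom(phantom_spec("shell", noise_sd = 0.05,
                                  bias_coef = c(0, .1, 0, 0, .1, 0, 0, 0, 0, 0)))
  wm <- ph$labels$data == 3L
  n1 <- normalize_intensity(ph$intensity, wm)
  n2 <- normalize_intensity(n1, wm)
  expect_lt(sqrt(mean((n2$data - n1$data)^2)) / sqrt(mean(n1$data^2)), 0.001)

  one <- array(FALSE, dim(ph$intensity$data)); one[5, 5, 5] <- TRUE
  expect_error(normalize_intensity(ph$intensity, one), "mask too small")
  expect_error(normalize_intensity(ph$intensity,
                                   array(FALSE, dim(ph$intensity$data))),
               "empty mask")
  neg <- ph$intensity; neg$data[wm][1] <- -1
  expect_error(normalize_intensity(neg, wm), "non-positive")
})

test_that("mask dilation follows 6-connectivity and composes additively", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  expect_identical(dilate_mask(m, 0), m)
  d1 <- dilate_mask(m, 1)
  expect_identical(sum(d1), 7L)
  expect_true(all(d1[m]))  # monotone: output contains input
  full <- array(TRUE, c(5, 5, 5))
  expect_identical(dilate_mask(full, 3), full)
  expect_identical(dilate_mask(dilate_mask(m, 1), 2), dilate_mask(m, 3))
  expect_error(dilate_mask(m, -1), ">= 0")
})

test_that("apply_mask zeroes exactly the complement", {
  sc <- shell_case()
  vol <- sc$ph$intensity
  expect_identical(apply_mask(vol, array(TRUE, dim(vol$data)))$data, vol$data)
  expect_true(all(apply_mask(vol, array(FALSE, dim(vol$data)))$data == 0))
  bm <- sc$ph$truth$brain_mask
  out <- apply_mask(vol, bm)
  expect_identical(sum(out$data[!bm] != 0), 0L)
  expect_identical(out$data[bm], vol$data[bm])
  expect_error(apply_mask(vol, array(TRUE, c(2, 2, 2))), "shape")
})
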