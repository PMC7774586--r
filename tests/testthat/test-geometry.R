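test_that("interface distances honour the half-voxel face convention on a slab", {
  sc <- slab_case()
  dst <- sc$geo$distances
  lab <- sc$ph$labels$data
  gm <- dst$gm_mask
  # GM voxels whose -z neighbour is WM sit half a voxel from the interface
  below_wm <- laminargm:::shift_axis(lab == 3L, 3, 1L) & gm
  expect_lt(max(abs(dst$d_wm$data[below_wm] - 0.35)), 1e-3)
  # d_wm + d_csf equals the labelled ribbon extent (4.2 mm for a 4 mm slab
  # at 0.7 mm), within half a voxel of the nominal thickness everywhere
  tot <- dst$d_wm$data[gm] + dst$d_csf$data[gm]
  expect_lt(max(abs(tot - 4.2)), 1e-3)
  expect_lt(max(abs(tot - 4)), 0.35)
})

test_that("degenerate segmentations raise interface errors", {
  sc <- slab_case()
  lab <- sc$ph$labels
  no_csf <- lab; no_csf$data[no_csf$data == 1L] <- 0L
  expect_error(interface_distances(no_csf), "GM-CSF")
  no_wm <- lab; no_wm$data[no_wm$data == 3L] <- 0L
  expect_error(interface_distances(no_wm), "WM-GM")
  no_gm <- lab; no_gm$data[no_gm$data == 2L] <- 1L
  expect_error(interface_distances(no_gm), "no GM")
})

test_that("equidistant depth has the documented boundary behaviour", {
  mk <- function(a) volume_grid(array(a, c(2, 2, 2)), spacing = 1)
  expect_equal(equidistant_depth(mk(1.5), mk(1.5))$data[1], 0.5)
  expect_equal(equidistant_depth(mk(0), mk(2))$data[1], 0)
  expect_equal(equidistant_depth(mk(2), mk(0))$data[1], 1)
  expect_error(equidistant_depth(mk(0), mk(0)), "inconsistent segmentation")
})

test_that("equi-volume depth matches the analytic shell fraction and the flat limit", {
  # worked example: voxel at radius 8.5 in a 7-10 mm shell; the frustum
  # model value sits within 0.01 of the exact volume fraction 0.41267
  mk <- function(a) volume_grid(array(a, c(1, 1, 1)), spacing = 1)
  a <- equivolume_depth(mk(1.5), mk(1.5), mk(1 / 8.5))$data[1]
  expect_lt(abs(a - 0.4126712), 0.01)
  expect_gt(a, 0.4126712)        # frustum slightly overshoots the sphere
  # zero curvature reduces exactly to the equidistant fraction
  expect_equal(equivolume_depth(mk(1.2), mk(2.1), mk(0))$data[1],
               1.2 / 3.3, tolerance = 1e-12)
  expect_error(equivolume_depth(mk(1), mk(1), mk(NaN)), "non-finite curvature")

  sc <- shell_case()
  gm <- sc$ph$truth$gm_mask
  err <- sc$geo$depth$data[gm] - sc$ph$truth$depth$data[gm]
  expect_lt(median(abs(err)), 0.02)
  expect_true(all(sc$geo$depth$data[gm] >= 0 & sc$geo$depth$data[gm] <= 1))

  sl <- slab_case()
  gms <- sl$ph$truth$gm_mask
  expect_lt(max(abs(sl$geo$depth$data[gms] -
                      sl$geo$depth_equidistant$data[gms])), 1e-3)
})

test_that("equidistant depth shows the known convexity bias the equi-volume map removes", {
  sc <- shell_case()
  gm <- sc$ph$truth$gm_mask
  truth <- sc$ph$truth$depth$data[gm]
  bias_eqd <- median(sc$geo$depth_equidistant$data[gm] - truth)
  bias_eqv <- median(abs(sc$geo$depth$data[gm] - truth))
  expect_gt(bias_eqd, 0.03)
  expect_lt(bias_eqv, 0.02)
})

test_that("mean curvature is zero on slabs, 1/r on shells, sign-correct on folds", {
  sl <- slab_case()
  gm <- sl$ph$truth$gm_mask
  expect_lt(max(abs(sl$geo$curvature$data[gm])), 0.01)

  sc <- shell_case()
  gmr <- sc$ph$truth$gm_mask
  r <- voxel_radius(sc$ph$labels)
  mid <- gmr & abs(r - 8.5) < 0.35
  Hbar <- mean(sc$geo$curvature$data[mid])
  expect_lt(abs(Hbar * 8.5 - 1), 0.1)

  fc <- folded_case()
  gmf <- fc$ph$truth$gm_mask
  Ht <- fc$ph$truth$curvature$data
  He <- fc$geo$curvature$data
  w <- laminargm:::grid_world(fc$ph$labels)
  interior <- abs(w$x) < 0.55 * max(w$x) & abs(w$y) < 0.55 * max(w$y)
  big <- gmf & interior & abs(Ht) > 0.1
  expect_gt(mean(sign(He[big]) == sign(Ht[big])), 0.95)
})

test_that("local thickness recovers the nominal ribbon thickness", {
  sl <- slab_case()
  th <- sl$geo$thickness$data[sl$ph$truth$gm_mask]
  expect_true(all(th > 0))
  expect_true(all(abs(th - 4) <= 0.35))
  sc <- shell_case()
  ths <- sc$geo$thickness$data[sc$ph$truth$gm_mask]
  expect_true(all(ths > 0))
  expect_lt(abs(median(ths) - 3), 0.2)
  expect_gt(mean(abs(ths - 3) <= 0.35), 0.95)
})

test_that("depth increases monotonically along WM-to-CSF rays", {
  sl <- slab_case()
  d <- dim(sl$geo$depth$data)
  for (i in c(5, floor(d[1] / 2))) {
    ray <- sl$geo$depth$data[i, floor(d[2] / 2), ]
    ray <- ray[!is.na(ray)]
    expect_true(all(diff(ray) > 0))
  }
  sc <- shell_case()
  ctr <- (dim(sc$geo$depth$data) + 1) / 2
  ray <- sc$geo$depth$data[ctr[1]:dim(sc$geo$depth$data)[1], ctr[2], ctr[3]]
  ray <- ray[!is.na(ray)]
  expect_true(all(diff(ray) >= -1e-9))
})

test_that("shell depth error shrinks with finer voxels", {
  errs <- vapply(c(1.0, 0.7, 0.5), function(sp) {
    ph <- make_phantom(phantom_spec("shell", spacing_mm = sp, noise_sd = 0))
    geo <- suppressMessages(laminar_geometry(ph$labels))
    gm <- ph$truth$gm_mask
    median(abs(geo$depth$data[gm] - ph$truth$depth$data[gm]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
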