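test_that("detrended z-maps are centred, scaled and orthogonal to the regressors", {
  ph <- make_phantom(phantom_spec("folded", curvature_coeff = 2,
                                  thickness_coeff = 0.5,
                                  thickness_mod_amplitude_mm = 0.8,
                                  noise_sd = 0.1, seed = 2))
  gm <- ph$truth$gm_mask
  z <- detrend_gm(ph$intensity, ph$truth$curvature, ph$truth$thickness, gm)
  zz <- z$zvol$data[gm]
  expect_lt(abs(mean(zz)), 1e-8)
  expect_lt(abs(sd(zz) - 1), 1e-8)
  expect_lt(abs(cor(zz, ph$truth$curvature$data[gm])), 1e-8)
  expect_lt(abs(cor(zz, ph$truth$thickness$data[gm])), 1e-8)
  # imposed confound slopes are recovered
  expect_lt(abs(z$coefficients["curvature"] / 2 - 1), 0.05)
  expect_lt(abs(z$coefficients["thickness"] / 0.5 - 1), 0.05)
})

test_that("degenerate detrending inputs raise the documented errors", {
  # intensity exactly a + b*curvature + c*thickness: zero residual SD
  ph <- make_phantom(phantom_spec("folded", curvature_coeff = 2,
                                  thickness_coeff = 0.5,
                                  thickness_mod_amplitude_mm = 0.8,
                                  intensity_profile = function(d) rep(1.5, length(d)),
                                  noise_sd = 0))
  gm <- ph$truth$gm_mask
  expect_error(detrend_gm(ph$intensity, ph$truth$curvature,
                          ph$truth$thickness, gm),
               "constant residuals")
  # constant regressors -> collinear with the intercept
  phn <- make_phantom(phantom_spec("folded", noise_sd = 0.1))
  const <- phn$truth$curvature
  const$data[phn$truth$gm_mask] <- 1
  const2 <- phn$truth$thickness
  const2$data[phn$truth$gm_mask] <- 2
  expect_error(detrend_gm(phn$intensity, const, const2, phn$truth$gm_mask),
               "condition number")
})

test_that("ROI voxel selection implements the quantile and depth-window rule", {
  d <- c(4, 2, 2)
  pr <- volume_grid(array(c(seq(0.1, 1, 0.1), rep(0, 6)), d), spacing = 1)
  gm <- array(TRUE, d)
  depth_at <- function(x) laminargm:::new_depth_map(
    volume_grid(array(x, d), spacing = 1), "equivolume")
  # type-7 quantile of 0.1..1.0 at 0.25 is 0.325; strict > leaves 7 voxels
  expect_identical(length(select_roi_voxels(pr, depth_at(0.5), gm)), 7L)
  # depth window excludes everything at depth 0.9
  expect_identical(length(select_roi_voxels(pr, depth_at(0.9), gm)), 0L)
  # endpoints are inclusive
  expect_identical(length(select_roi_voxels(pr, depth_at(0.4), gm)), 7L)
  expect_identical(length(select_roi_voxels(pr, depth_at(0.6), gm)), 7L)
  empty <- volume_grid(array(0, d), spacing = 1)
  expect_error(select_roi_voxels(empty, depth_at(0.5), gm),
               "positive-probability")
})

test_that("selection is monotone in the quantile and depth window", {
  set.seed(8)
  d <- c(6, 6, 6)
  gm <- array(TRUE, d)
  for (rep in 1:5) {
    pr <- volume_grid(array(runif(prod(d)) * (runif(prod(d)) > 0.3), d),
                      spacing = 1)
    dep <- laminargm:::new_depth_map(
      volume_grid(array(runif(prod(d)), d), spacing = 1), "equivolume")
    base <- select_roi_voxels(pr, dep, gm)
    lower_q <- select_roi_voxels(pr, dep, gm, prob_quantile = 0.1)
    wider_w <- select_roi_voxels(pr, dep, gm, depth_window = c(0.3, 0.7))
    expect_true(all(base %in% lower_q))
    expect_true(all(base %in% wider_w))
  }
})

test_that("ROI aggregation averages the selected voxels", {
  d <- c(3, 1, 1)
  z <- volume_grid(array(c(-1, 0, 1), d), spacing = 1)
  th <- volume_grid(array(c(2, 3, 4), d), spacing = 1)
  ag <- aggregate_roi(z, th, 1:3)
  expect_equal(ag$mean_z_gm, 0)
  expect_equal(ag$mean_thickness_mm, 3)
  expect_identical(ag$n_voxels, 3L)
  expect_equal(aggregate_roi(z, th, 2L)$mean_z_gm, 0)
  expect_identical(aggregate_roi(z, th, integer(0))$n_voxels, 0L)
  expect_true(is.na(aggregate_roi(z, th, integer(0))$mean_z_gm))
})

test_that("nearest-neighbour atlas resampling preserves values", {
  sc <- shell_case()
  atlas <- make_phantom_atlas(sc$ph$labels, n_roi = 8)
  same <- atlas_to_subject(atlas, diag(4), sc$ph$labels)
  for (id in names(atlas$prob))
    expect_identical(same$prob[[id]]$data, atlas$prob[[id]]$data)
  # translation by exactly one voxel shifts the field
  A <- diag(4); A[1, 4] <- sc$ph$labels$spacing[1]
  sh <- atlas_to_subject(atlas, A, sc$ph$labels)
  id <- names(atlas$prob)[1]
  d <- dim(atlas$prob[[id]]$data)
  expect_equal(sh$prob[[id]]$data[2:d[1], , ],
               atlas$prob[[id]]$data[1:(d[1] - 1), , ])
  # nearest neighbour introduces no new values
  expect_true(all(sh$prob[[id]]$data %in% c(atlas$prob[[id]]$data, 0)))
  expect_error(atlas_to_subject(atlas, matrix(0, 4, 4), sc$ph$labels),
               "singular")
})

test_that("feature tables have one deterministic row per participant and ROI", {
  spec <- cohort_spec(n_per_group = c(control = 2, CHR = 1), seed = 9)
  sim <- simulate_cohort_volumes(spec, phantom_spec("folded", noise_sd = 0.1),
                                 n_roi = 8)
  parts <- lapply(sim$participants, function(ph) {
    geo <- suppressMessages(laminar_geometry(ph$labels))
    z <- detrend_gm(ph$intensity, geo$curvature, geo$thickness,
                    ph$truth$gm_mask)
    list(z = z, depth = geo$depth, thickness = geo$thickness,
         gm_mask = ph$truth$gm_mask)
  })
  tab <- build_feature_table(parts, sim$atlas, sim$covariates)
  expect_identical(nrow(tab), 3L * 8L)
  expect_identical(anyDuplicated(tab[c("participant_id", "roi_id")]), 0L)
  # shuffled input order gives the identical table
  tab2 <- build_feature_table(parts[rev(names(parts))], sim$atlas,
                              sim$covariates[sample(3), ])
  expect_identical(tab, tab2)
  expect_error(build_feature_table(parts, sim$atlas,
                                   sim$covariates[-1, ]),
               "missing from covariates")
  # a 70-ROI atlas yields 70 rows per participant (table-level generator)
  tab70 <- simulate_cohort(cohort_spec(n_per_group = c(control = 2, CHR = 2)),
                           dk_atlas_meta())
  expect_identical(nrow(tab70), 4L * 70L)
})

test_that("imposed frontal offsets are recovered from the feature table", {
  eff <- data.frame(group = "CHR", lobe = "frontal", offset = -0.5)
  spec <- cohort_spec(n_per_group = c(control = 20, CHR = 20),
                      effect_by_lobe = eff, seed = 21)
  sim <- simulate_cohort_volumes(spec, phantom_spec("folded", noise_sd = 0.1))
  parts <- lapply(sim$participants, function(ph) {
    geo <- suppressMessages(laminar_geometry(ph$labels))
    z <- detrend_gm(ph$intensity, geo$curvature, geo$thickness,
                    ph$truth$gm_mask)
    list(z = z, depth = geo$depth, thickness = geo$thickness,
         gm_mask = ph$truth$gm_mask)
  })
  tab <- build_feature_table(parts, sim$atlas, sim$covariates)
  d <- lobe_differential_effect(tab, "frontal", c("CHR", "control"))
  expect_lt(abs(d$estimate - (-0.5)), 0.1)
})
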