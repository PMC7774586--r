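test_that("the mixed model reports conditional F-tests and variance components", {
  tab <- simulate_cohort(calib_cohort(1), meta16())
  fit <- suppressMessages(fit_group_lme(tab))
  expect_s3_class(fit, "laminar_lme")
  expect_true(all(c("group", "lobe", "group:lobe") %in% fit$anova_table$term))
  expect_true(all(fit$anova_table$p >= 0 & fit$anova_table$p <= 1))
  expect_true(all(fit$anova_table$numDF > 0 & fit$anova_table$denDF > 0))
  expect_gte(fit$random_intercept_sd, 0)
  expect_gt(fit$residual_sd, 0)
  expect_identical(fit$n_participants, 60L)
  ift <- interaction_ftest(fit)
  expect_identical(nrow(ift), 1L)
  expect_equal(ift$numDF, 6)
  # print and coef methods work
  expect_output(print(fit), "Conditional F-tests")
  expect_true("(Intercept)" %in% names(coef(fit)))
})

test_that("variance components are recovered at n = 100 participants", {
  spec <- cohort_spec(n_per_group = c(control = 34, CHR = 33,
                                      `CHR-negative` = 33),
                      random_intercept_sd = 0.4, residual_sd = 0.5,
                      seed = 17)
  fit <- suppressMessages(fit_group_lme(simulate_cohort(spec, meta16())))
  expect_gt(fit$random_intercept_sd, 0.3)
  expect_lt(fit$random_intercept_sd, 0.5)
  expect_lt(abs(fit$residual_sd - 0.5), 0.05)
})

test_that("fixed group effects injected by the simulator are recovered with small bias", {
  eff <- data.frame(group = c("CHR", "CHR"), lobe = c("frontal", "occipital"),
                    offset = c(-0.5, 0.3))
  spec <- cohort_spec(n_per_group = c(control = 50, CHR = 50),
                      effect_by_lobe = eff, seed = 23)
  fit <- suppressMessages(fit_group_lme(simulate_cohort(spec, meta16())))
  cf <- coef(fit)
  # reference lobe is frontal (alphabetical): groupCHR is the frontal contrast
  expect_lt(abs(cf[["groupCHR"]] - (-0.5)), 0.2)
  expect_lt(abs(cf[["groupCHR:lobeoccipital"]] - 0.8), 0.25)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- simulate_cohort(calib_cohort(2, n = 5), meta16())
  one <- tab[tab$group == "CHR", ]
  one$group <- factor(one$group)
  expect_error(suppressMessages(fit_group_lme(one, reference_group = "CHR")),
               "at least 2 groups")
  const <- tab; const$mean_z_gm <- 1
  expect_error(suppressMessages(fit_group_lme(const)), "zero-variance")
  gap <- tab[!(tab$group == "CHR" & tab$lobe == "frontal"), ]
  expect_error(suppressMessages(fit_group_lme(gap)), "missing group x lobe")
  expect_error(suppressMessages(fit_group_lme(tab, outcome = "nope")),
               "lacks columns")
})

test_that("Satterthwaite denominator df agrees with containment on balanced designs", {
  skip_if_not_installed("lmerTest")
  tab <- simulate_cohort(calib_cohort(3, n = 10), meta16())
  f1 <- suppressMessages(fit_group_lme(tab))
  f2 <- suppressMessages(fit_group_lme(tab, ddf = "satterthwaite"))
  F1 <- interaction_ftest(f1)$F
  F2 <- interaction_ftest(f2)$F
  expect_lt(abs(F1 / F2 - 1), 0.05)
})

test_that("per-lobe contrasts correct across lobes and respect correction dominance", {
  eff <- data.frame(group = "CHR", lobe = "frontal", offset = -0.5)
  tab <- simulate_cohort(calib_cohort(5, n = 40, effect = eff), meta16())
  pc_b <- suppressMessages(per_lobe_contrasts(tab, correction = "bonferroni"))
  pc_h <- suppressMessages(per_lobe_contrasts(tab, correction = "holm"))
  expect_identical(nrow(pc_b), 8L)    # 4 lobes x 2 non-reference groups
  expect_true(all(pc_b$p_corrected >= pc_b$p))
  expect_true(all(pc_b$p_corrected >= pc_h$p_corrected - 1e-12))
  expect_true(all(pc_h$p_corrected >= pc_h$p))
  fr <- pc_b$lobe == "frontal" & pc_b$contrast == "CHR vs control"
  expect_lt(pc_b$p_corrected[fr], 0.05)
  expect_lt(abs(pc_b$estimate[fr] - (-0.5)), 0.25)
  # single-lobe family: corrected p equals raw p
  pc1 <- suppressMessages(per_lobe_contrasts(tab, lobes = "frontal"))
  expect_equal(pc1$p_corrected, pc1$p)
  expect_error(suppressMessages(per_lobe_contrasts(tab, lobes = "limbic")),
               "unknown lobe")
  # participant-mean unit gives compatible estimates
  pcp <- suppressMessages(per_lobe_contrasts(tab, unit = "participant"))
  frp <- pcp$lobe == "frontal" & pcp$contrast == "CHR vs control"
  expect_lt(abs(pcp$estimate[frp] - pc_b$estimate[fr]), 0.1)
})

test_that("lobe statistics are invariant to relabelling ROI ids", {
  eff <- data.frame(group = "CHR", lobe = "frontal", offset = -0.4)
  tab <- simulate_cohort(calib_cohort(6, n = 15, effect = eff), meta16())
  tab2 <- tab
  map <- setNames(paste0("roi", seq_along(unique(tab$roi_id))),
                  unique(tab$roi_id))
  tab2$roi_id <- unname(map[tab2$roi_id])
  pc1 <- suppressMessages(per_lobe_contrasts(tab))
  pc2 <- suppressMessages(per_lobe_contrasts(tab2))
  expect_equal(pc1, pc2)
  f1 <- suppressMessages(fit_group_lme(tab))
  f2 <- suppressMessages(fit_group_lme(tab2))
  expect_equal(f1$anova_table, f2$anova_table)
})

test_that("post-hoc Welch t-tests behave as documented", {
  tab <- simulate_cohort(calib_cohort(7, n = 10), meta16())
  roi <- tab$roi_id[1]
  same <- tab[tab$roi_id == roi & tab$group %in% c("control", "CHR"), ]
  same$mean_z_gm <- rep(seq_len(10), 2)[seq_len(nrow(same))]
  same$mean_z_gm[same$group == "CHR"] <- same$mean_z_gm[same$group == "control"]
  tt0 <- posthoc_roi_ttests(same, roi, c("control", "CHR"))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  tt1 <- posthoc_roi_ttests(tab, roi, c("control", "CHR"))
  tt2 <- posthoc_roi_ttests(tab, roi, c("CHR", "control"))
  expect_equal(tt1$t, -tt2$t)
  expect_equal(tt1$p, tt2$p)
  tiny <- tab[tab$participant_id %in% unique(tab$participant_id)[1], ]
  expect_error(posthoc_roi_ttests(tiny, roi, c("control", "CHR")),
               "fewer than 2")
})

test_that("post-hoc tests detect a large standardized offset", {
  hits <- 0L
  for (i in 1:20) {
    spec <- cohort_spec(n_per_group = c(control = 30, CHR = 30),
                        random_intercept_sd = 0, residual_sd = 0.5, seed = i)
    tab <- simulate_cohort(spec, meta16())
    roi <- "lh_frontal_1"
    tab$mean_z_gm[tab$roi_id == roi & tab$group == "CHR"] <-
      tab$mean_z_gm[tab$roi_id == roi & tab$group == "CHR"] + 1.0
    tt <- posthoc_roi_ttests(tab, roi, c("CHR", "control"))
    if (abs(tt$t) > 4) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("covariate-adjusted correlations recover imposed partial correlations", {
  tab <- simulate_cohort(calib_cohort(8, n = 10), meta16())
  per <- unique(tab[c("participant_id")])
  # outcome equal to the covariate: partial r = 1
  outc <- vapply(split(tab$mean_z_gm, tab$participant_id), mean, 1)
  cov_tab <- data.frame(participant_id = names(outc), score = unname(outc))
  res <- covariate_adjusted_correlation(tab, cov_tab)
  expect_equal(res$partial_r, 1, tolerance = 1e-12)
  expect_error(covariate_adjusted_correlation(
    tab, transform(cov_tab, score = 1)), "zero variance")
  expect_error(covariate_adjusted_correlation(tab, cov_tab, scope = "limbic"),
               "unknown scope")

  # imposed partial correlation r = 0.3 at n = 114 participants
  inside <- 0L
  reps <- 60L
  for (i in seq_len(reps)) {
    spec <- cohort_spec(n_per_group = c(control = 57, CHR = 57), seed = 100 + i)
    tb <- simulate_cohort(spec, meta16())
    om <- vapply(split(tb$mean_z_gm, tb$participant_id), mean, 1)
    set.seed(200 + i)
    sc <- 0.3 * scale(om)[, 1] + sqrt(1 - 0.09) * rnorm(length(om))
    cv <- data.frame(participant_id = names(om), score = sc)
    r <- covariate_adjusted_correlation(tb, cv)$partial_r
    if (r > 0.15 && r < 0.45) inside <- inside + 1L
  }
  expect_gte(inside / reps, 0.8)
})

test_that("correlation p-values are uniform under the null", {
  ps <- vapply(1:200, function(i) {
    spec <- cohort_spec(n_per_group = c(control = 25, CHR = 25),
                        seed = 300 + i)
    tb <- simulate_cohort(spec, meta16())
    om <- vapply(split(tb$mean_z_gm, tb$participant_id), mean, 1)
    set.seed(400 + i)
    cv <- data.frame(participant_id = names(om), score = rnorm(length(om)))
    covariate_adjusted_correlation(tb, cv)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
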