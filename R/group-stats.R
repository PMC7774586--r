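# Group inference on the participant x ROI feature table: linear
# mixed-effects model with participant random intercepts and conditional
# F-tests, per-lobe linear models contrasting each group against the control
# intercept with multiplicity correction, post-hoc Welch t-tests, and
# covariate-adjusted (partial) correlations.

prep_model_frame <- function(table, outcome, reference_group) {
  need <- c("participant_id", "group", "lobe", "hemisphere", "age", "gender",
            outcome)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  df <- table[is.finite(table[[outcome]]), , drop = FALSE]
  dropped <- nrow(table) - nrow(df)
  if (dropped > 0)
    message("excluding ", dropped, " row(s) with missing ", outcome)
  if (!reference_group %in% df$group)
    stop("reference group '", reference_group, "' absent from table")
  df$group <- stats::relevel(factor(df$group), ref = reference_group)
  df$lobe <- factor(df$lobe)
  df$hemisphere <- factor(df$hemisphere)
  df$gender <- factor(df$gender)
  df$age_c <- df$age - mean(df$age)
  df$.outcome <- df[[outcome]]
  df
}

#' Fit the group x lobe mixed-effects model
#'
#' Fits `outcome ~ group * lobe + hemisphere + age + gender` with a random
#' intercept per participant by REML, and reports conditional F-tests for
#' every fixed term (sequential, containment denominator degrees of freedom
#' as in `nlme`); a Satterthwaite alternative via `lmerTest` is available.
#' The reference level of `group` is the control group, so group
#' coefficients are contrasts against the control intercept.
#'
#' @param table long-format feature table (see [build_feature_table()] /
#'   [simulate_cohort()]).
#' @param outcome outcome column, `"mean_z_gm"` (default) or
#'   `"mean_thickness_mm"`.
#' @param reference_group control group label.
#' @param ddf denominator-df method: `"containment"` (nlme) or
#'   `"satterthwaite"` (requires lmerTest).
#' @return Object of class `laminar_lme`: list with `fixed_effects`
#'   (estimate, SE, t per coefficient), `anova_table` (term, numDF, denDF,
#'   F, p), `random_intercept_sd`, `residual_sd`, `n_participants`,
#'   `n_rows`, and the underlying `fit`.
#' @export
fit_group_lme <- function(table, outcome = "mean_z_gm",
                          reference_group = "control",
                          ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  df <- prep_model_frame(table, outcome, reference_group)
  if (nlevels(df$group) < 2) stop("need at least 2 groups")
  if (nlevels(df$lobe) < 2) stop("need at least 2 lobes")
  tt <- table(unique(df[c("participant_id", "group")])$group)
  if (any(tt < 2)) stop("need at least 2 participants per group")
  if (var(df$.outcome) < 1e-14) stop("zero-variance outcome; singular fit")
  cells <- table(df$group, df$lobe)
  if (any(cells == 0)) {
    gaps <- which(cells == 0, arr.ind = TRUE)
    stop("missing group x lobe cells: ",
         paste(sprintf("%s/%s", rownames(cells)[gaps[, 1]],
                       colnames(cells)[gaps[, 2]]), collapse = ", "))
  }
  has_gender <- nlevels(df$gender) > 1
  has_hemi <- nlevels(df$hemisphere) > 1
  rhs <- paste(c("group * lobe", if (has_hemi) "hemisphere", "age_c",
                 if (has_gender) "gender"), collapse = " + ")
  form <- as.formula(paste(".outcome ~", rhs))

  if (ddf == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("ddf = 'satterthwaite' requires the lmerTest package")
    lform <- stats::update(form, . ~ . + (1 | participant_id))
    fit <- lmerTest::lmer(lform, data = df, REML = TRUE)
    an <- stats::anova(fit, type = 1)
    anova_table <- data.frame(term = rownames(an), numDF = an$NumDF,
                              denDF = an$DenDF, F = an$`F value`,
                              p = an$`Pr(>F)`, stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_sd <- vc$sdcor[vc$grp == "participant_id"][1]
    res_sd <- vc$sdcor[vc$grp == "Residual"][1]
    cf <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], t = cf[, "t value"],
                        stringsAsFactors = FALSE)
  } else {
    fit <- nlme::lme(fixed = form, random = ~ 1 | participant_id, data = df,
                     method = "REML")
    an <- stats::anova(fit)   # sequential conditional F-tests
    anova_table <- data.frame(term = rownames(an), numDF = an$numDF,
                              denDF = an$denDF, F = an$`F-value`,
                              p = an$`p-value`, stringsAsFactors = FALSE)
    vc <- nlme::VarCorr(fit)
    ri_sd <- as.numeric(vc["(Intercept)", "StdDev"])
    res_sd <- fit$sigma
    cf <- summary(fit)$tTable
    fixed <- data.frame(term = rownames(cf), estimate = cf[, "Value"],
                        se = cf[, "Std.Error"], t = cf[, "t-value"],
                        stringsAsFactors = FALSE)
  }
  rownames(fixed) <- rownames(anova_table) <- NULL
  structure(list(fixed_effects = fixed, anova_table = anova_table,
                 random_intercept_sd = ri_sd, residual_sd = res_sd,
                 n_participants = length(unique(df$participant_id)),
                 n_rows = nrow(df), outcome = outcome,
                 reference_group = reference_group, ddf = ddf, fit = fit),
            class = "laminar_lme")
}

#' @export
print.laminar_lme <- function(x, ...) {
  cat(sprintf(
    "Linear mixed model for %s (%d participants, %d rows; reference '%s')\n",
    x$outcome, x$n_participants, x$n_rows, x$reference_group))
  cat(sprintf(
    "Random intercept SD %.4f, residual SD %.4f\nConditional F-tests (%s df):\n",
    x$random_intercept_sd, x$residual_sd, x$ddf))
  print(x$anova_table, digits = 4)
  invisible(x)
}

#' @export
summary.laminar_lme <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  print(object$fixed_effects, digits = 4)
  invisible(object)
}

#' @export
coef.laminar_lme <- function(object, ...) {
  setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' Interaction F-test helper
#'
#' Extracts the group x lobe conditional F-test row from a fitted
#' [fit_group_lme()] object.
#'
#' @param fit a `laminar_lme`.
#' @return One-row data.frame (term, numDF, denDF, F, p).
#' @export
interaction_ftest <- function(fit) {
  stopifnot(inherits(fit, "laminar_lme"))
  an <- fit$anova_table
  an[grepl("group:lobe|group x lobe", an$term), , drop = FALSE]
}

#' Per-lobe group contrasts against the control intercept
#'
#' Fits a separate linear model per lobe,
#' `outcome ~ group + hemisphere + age + gender`, and reports each
#' non-reference group's coefficient as a T contrast against the control
#' intercept. By default the model uses ROI-level rows with
#' participant-clustered (CR robust) standard errors; alternatively each
#' participant is first averaged within the lobe. P-values are corrected
#' across the lobes within each group-contrast family (default Bonferroni).
#'
#' @param table feature table.
#' @param outcome outcome column.
#' @param reference_group control group label.
#' @param correction `p.adjust` method across lobes (default
#'   `"bonferroni"`; `"holm"`, `"BH"`, ... also accepted).
#' @param unit `"roi"` (ROI-level rows, clustered SEs) or `"participant"`
#'   (participant lobe means, ordinary SEs).
#' @param lobes lobes to model; default all in the table.
#' @return data.frame with lobe, contrast, estimate, se, t, df, p,
#'   p_corrected, correction_method.
#' @export
per_lobe_contrasts <- function(table, outcome = "mean_z_gm",
                               reference_group = "control",
                               correction = "bonferroni",
                               unit = c("roi", "participant"),
                               lobes = NULL) {
  unit <- match.arg(unit)
  df <- prep_model_frame(table, outcome, reference_group)
  all_lobes <- levels(df$lobe)
  if (is.null(lobes)) lobes <- all_lobes
  bad <- setdiff(lobes, all_lobes)
  if (length(bad)) stop("unknown lobe(s): ", paste(bad, collapse = ", "))
  res <- NULL
  for (lb in lobes) {
    d <- df[df$lobe == lb, , drop = FALSE]
    d$group <- droplevels(d$group)
    if (unit == "participant") {
      agg <- stats::aggregate(.outcome ~ participant_id + group + age_c +
                                gender, data = d, FUN = mean)
      m <- lm(.outcome ~ group + age_c + gender, data = agg)
      ct <- lmtest::coeftest(m)
    } else {
      m <- lm(.outcome ~ group + hemisphere + age_c + gender, data = d)
      vc <- sandwich::vcovCL(m, cluster = d$participant_id)
      dfree <- max(length(unique(d$participant_id)) - length(coef(m)), 1L)
      ct <- lmtest::coeftest(m, vcov. = vc, df = dfree)
    }
    gterms <- grep("^group", rownames(ct), value = TRUE)
    for (g in gterms) {
      res <- rbind(res, data.frame(
        lobe = lb,
        contrast = paste(sub("^group", "", g), "vs", reference_group),
        estimate = ct[g, 1L], se = ct[g, 2L],
        t = ct[g, 3L], p = ct[g, 4L],
        stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- NULL
  res$p_corrected <- NA_real_
  for (cn in unique(res$contrast)) {
    i <- res$contrast == cn
    res$p_corrected[i] <- p.adjust(res$p[i], method = correction)
  }
  res$correction_method <- correction
  res
}

#' Differential lobe effect between two groups
#'
#' Because z-scored GM is centred on each participant's own mean, a regional
#' intensity offset is identified only relative to the rest of the cortex.
#' This helper computes, per participant, the mean outcome in the target
#' lobe minus the mean outcome in all other lobes, and contrasts the two
#' groups on that differential (first group minus second), with a
#' participant-level standard error. It is the quantity that an injected
#' per-lobe offset is expected to reproduce.
#'
#' @param table feature table.
#' @param lobe target lobe.
#' @param groups length-2 character: groups contrasted (first minus second).
#' @param outcome outcome column.
#' @return List with `estimate`, `se`, `n` (participants per group).
#' @export
lobe_differential_effect <- function(table, lobe = "frontal", groups,
                                     outcome = "mean_z_gm") {
  if (!lobe %in% table$lobe) stop("unknown lobe '", lobe, "'")
  if (length(groups) != 2) stop("groups must name exactly 2 groups")
  d <- table[is.finite(table[[outcome]]), , drop = FALSE]
  per <- vapply(split(d, d$participant_id), function(p)
    mean(p[[outcome]][p$lobe == lobe]) -
      mean(p[[outcome]][p$lobe != lobe]), numeric(1))
  grp <- d$group[match(names(per), d$participant_id)]
  x <- per[grp == groups[1]]; y <- per[grp == groups[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 participants per group")
  list(estimate = mean(x) - mean(y),
       se = sqrt(var(x) / length(x) + var(y) / length(y)),
       n = c(length(x), length(y)))
}

#' Post-hoc per-ROI Welch t-tests
#'
#' Two-sided Welch two-sample t-tests on participant-level ROI means between
#' two groups.
#'
#' @param table feature table.
#' @param roi_ids ROIs to test; default all.
#' @param groups length-2 character, the two groups compared (first minus
#'   second).
#' @param outcome outcome column.
#' @return data.frame with roi_id, estimate (group difference), t, df, p.
#' @export
posthoc_roi_ttests <- function(table, roi_ids = NULL,
                               groups, outcome = "mean_z_gm") {
  if (length(groups) != 2) stop("groups must name exactly 2 groups")
  if (is.null(roi_ids)) roi_ids <- unique(table$roi_id)
  out <- NULL
  for (roi in roi_ids) {
    d <- table[table$roi_id == roi & table$group %in% groups &
                 is.finite(table[[outcome]]), , drop = FALSE]
    x <- d[[outcome]][d$group == groups[1]]
    y <- d[[outcome]][d$group == groups[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("fewer than 2 participants per group for ROI ", roi)
    tt <- t.test(x, y, alternative = "two.sided", var.equal = FALSE)
    out <- rbind(out, data.frame(
      roi_id = roi, estimate = mean(x) - mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted (partial) correlation
#'
#' Correlates a participant-level mean outcome (whole brain or one lobe)
#' with a per-participant covariate, after residualizing both on an
#' adjustment set (default age and gender). Two-sided p from the t
#' distribution of the partial correlation.
#'
#' @param table feature table.
#' @param covariate_table data.frame `participant_id`, `score` with the
#'   external covariate (e.g. functioning or symptom score).
#' @param outcome outcome column.
#' @param scope `"whole_brain"` or a lobe name.
#' @param adjust_for columns of the feature table used as adjustment
#'   covariates.
#' @return data.frame (class row) with scope, outcome, partial_r, df, p and
#'   the adjusted-for set.
#' @export
covariate_adjusted_correlation <- function(table, covariate_table,
                                           outcome = "mean_z_gm",
                                           scope = "whole_brain",
                                           adjust_for = c("age", "gender")) {
  d <- table[is.finite(table[[outcome]]), , drop = FALSE]
  if (scope != "whole_brain") {
    if (!scope %in% d$lobe) stop("unknown scope '", scope, "'")
    d <- d[d$lobe == scope, , drop = FALSE]
  }
  per <- stats::aggregate(d[[outcome]],
                          by = list(participant_id = d$participant_id),
                          FUN = mean)
  names(per)[2] <- "outcome"
  cov1 <- d[!duplicated(d$participant_id),
            c("participant_id", adjust_for), drop = FALSE]
  per <- merge(per, cov1, by = "participant_id")
  per <- merge(per, covariate_table, by = "participant_id")
  per <- per[complete.cases(per), , drop = FALSE]
  n <- nrow(per)
  if (n < length(adjust_for) + 3) stop("too few participants for adjustment")
  Xadj <- stats::model.matrix(
    as.formula(paste("~", paste(adjust_for, collapse = "+"))), data = per)
  r1 <- lm.fit(Xadj, per$outcome)$residuals
  r2 <- lm.fit(Xadj, per$score)$residuals
  if (var(r1) < 1e-14 || var(r2) < 1e-14)
    stop("zero variance after residualization")
  r <- cor(r1, r2)
  dfree <- n - ncol(Xadj) - 1
  tstat <- r * sqrt(dfree / (1 - r^2))
  p <- 2 * pt(-abs(tstat), dfree)
  data.frame(scope = scope, outcome = outcome, partial_r = r, df = dfree,
             p = p, adjusted_for = paste(adjust_for, collapse = ","),
             stringsAsFactors = FALSE)
}
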