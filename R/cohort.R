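# Multi-participant cohort simulation with the statistical structure the
# group model assumes: per-lobe means, group x lobe offsets, participant
# random intercepts and residual noise, plus demographic covariates.
#
# Default group sizes follow the study design this package emulates:
# 49 controls, 114 CHR, 39 CHR-negative (202 participants).

#' Specify a simulated cohort
#'
#' @param n_per_group named integer vector, participants per group; names are
#'   the group labels. The first name (or `reference`) is the control level.
#' @param reference reference ("control") group label; must have zero offset
#'   in every lobe.
#' @param effect_by_lobe data.frame with columns `group`, `lobe`, `offset`
#'   giving z-GM offsets for non-reference groups; NULL means no effects.
#' @param random_intercept_sd SD of the participant random intercept (z-GM
#'   units).
#' @param residual_sd residual SD per participant x ROI observation.
#' @param lobe_means baseline z-GM per lobe (occipital highest, frontal
#'   lowest, following the laminar myelination pattern of real cortex).
#' @param thickness_lobe_means baseline cortical thickness per lobe (mm).
#' @param thickness_intercept_sd,thickness_residual_sd variance components of
#'   the simulated thickness outcome (mm).
#' @param age_mean,age_sd Gaussian age distribution (years).
#' @param p_female probability of gender "female".
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 49, CHR = 114,
                                        `CHR-negative` = 39),
                        reference = names(n_per_group)[1],
                        effect_by_lobe = NULL,
                        random_intercept_sd = 0.3,
                        residual_sd = 0.5,
                        lobe_means = c(frontal = -0.25, parietal = 0.05,
                                       temporal = -0.05, occipital = 0.3),
                        thickness_lobe_means = c(frontal = 2.6,
                                                 parietal = 2.4,
                                                 temporal = 2.8,
                                                 occipital = 2.1),
                        thickness_intercept_sd = 0.1,
                        thickness_residual_sd = 0.15,
                        age_mean = 22, age_sd = 4.2,
                        p_female = 0.7, seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 1)) stop("group sizes must be >= 1")
  if (!reference %in% names(n_per_group))
    stop("reference group '", reference, "' not among groups")
  if (random_intercept_sd < 0 || residual_sd < 0 ||
      thickness_intercept_sd < 0 || thickness_residual_sd < 0)
    stop("all SDs must be >= 0")
  if (!is.null(effect_by_lobe)) {
    need <- c("group", "lobe", "offset")
    if (!all(need %in% names(effect_by_lobe)))
      stop("effect_by_lobe needs columns: ", paste(need, collapse = ", "))
    bad_grp <- setdiff(effect_by_lobe$group, names(n_per_group))
    if (length(bad_grp))
      stop("effect_by_lobe refers to unknown group(s): ",
           paste(bad_grp, collapse = ", "))
    ref_eff <- effect_by_lobe[effect_by_lobe$group == reference, ]
    if (nrow(ref_eff) && any(ref_eff$offset != 0))
      stop("reference group must have zero offset in every lobe")
  }
  structure(list(n_per_group = n_per_group, reference = reference,
                 groups = names(n_per_group),
                 effect_by_lobe = effect_by_lobe,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, lobe_means = lobe_means,
                 thickness_lobe_means = thickness_lobe_means,
                 thickness_intercept_sd = thickness_intercept_sd,
                 thickness_residual_sd = thickness_residual_sd,
                 age_mean = age_mean, age_sd = age_sd, p_female = p_female,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_effect_lookup <- function(spec, lobes) {
  eff <- matrix(0, nrow = length(spec$groups), ncol = length(lobes),
                dimnames = list(spec$groups, lobes))
  if (!is.null(spec$effect_by_lobe)) {
    bad <- setdiff(unique(spec$effect_by_lobe$lobe), lobes)
    if (length(bad))
      stop("effect_by_lobe refers to unknown lobe(s): ",
           paste(bad, collapse = ", "))
    for (r in seq_len(nrow(spec$effect_by_lobe)))
      eff[spec$effect_by_lobe$group[r], spec$effect_by_lobe$lobe[r]] <-
        spec$effect_by_lobe$offset[r]
  }
  eff
}

cohort_covariates <- function(spec) {
  groups <- rep(spec$groups, times = spec$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub%03d", seq_len(n))
  data.frame(participant_id = ids, group = groups,
             age = round(rnorm(n, spec$age_mean, spec$age_sd), 1),
             gender = ifelse(rbinom(n, 1, spec$p_female) == 1,
                             "female", "male"),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort feature table directly
#'
#' Draws one row per participant x ROI with
#' `z-GM = lobe mean + group x lobe offset + participant intercept + noise`,
#' where the intercept is N(0, random_intercept_sd^2) and the noise
#' N(0, residual_sd^2); cortical thickness is simulated analogously without
#' group effects. Covariates are sampled from the cohort specification's
#' distributions; fully reproducible under its seed.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a `prob_atlas` or an atlas metadata data.frame with columns
#'   `roi_id`, `hemisphere`, `lobe` (e.g. [dk_atlas_meta()]).
#' @return Long-format feature table as in [build_feature_table()].
#' @examples
#' tab <- simulate_cohort(cohort_spec(c(control = 3, CHR = 3)),
#'                        dk_atlas_meta())
#' nrow(tab)  # 6 participants x 70 ROIs
#' @export
simulate_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- if (inherits(atlas, "prob_atlas")) atlas$meta else atlas
  if (!all(c("roi_id", "hemisphere", "lobe") %in% names(meta)))
    stop("atlas metadata must have roi_id, hemisphere, lobe")
  eff <- cohort_effect_lookup(spec, unique(meta$lobe))
  local_seed(spec$seed, {
    cov <- cohort_covariates(spec)
    n <- nrow(cov)
    b <- rnorm(n, 0, spec$random_intercept_sd)
    bt <- rnorm(n, 0, spec$thickness_intercept_sd)
    k <- nrow(meta)
    tab <- data.frame(
      participant_id = rep(cov$participant_id, each = k),
      group = rep(cov$group, each = k),
      age = rep(cov$age, each = k),
      gender = rep(cov$gender, each = k),
      roi_id = rep(meta$roi_id, times = n),
      hemisphere = rep(meta$hemisphere, times = n),
      lobe = rep(meta$lobe, times = n),
      stringsAsFactors = FALSE)
    mu <- spec$lobe_means[tab$lobe] +
      eff[cbind(tab$group, tab$lobe)] + rep(b, each = k)
    tab$mean_z_gm <- mu + rnorm(n * k, 0, spec$residual_sd)
    tab$mean_thickness_mm <- spec$thickness_lobe_means[tab$lobe] +
      rep(bt, each = k) + rnorm(n * k, 0, spec$thickness_residual_sd)
    tab$n_voxels_selected <- rpois(n * k, 60)
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate a cohort of phantom volumes
#'
#' Generates one phantom per participant, injecting the cohort's group x lobe
#' z-GM offsets as regional intensity offsets scaled by the phantom's
#' detrended GM intensity SD (computed analytically from the noise-free truth
#' fields), plus a participant-level global intensity intercept. Enables
#' end-to-end pipeline recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param phantom a [phantom_spec()] shared by all participants (noise seeds
#'   differ per participant, derived from the cohort seed).
#' @param n_roi ROIs in the synthetic atlas (multiple of 8).
#' @return List with `participants` (list of `phantom` objects named by id),
#'   `covariates` (data.frame), `atlas` (the `prob_atlas` used), and
#'   `z_unit_sd` (raw-intensity SD corresponding to one z unit).
#' @export
simulate_cohort_volumes <- function(spec, phantom, n_roi = 16) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(phantom, "phantom_spec"))
  template <- make_phantom(phantom)
  atlas <- make_phantom_atlas(template$labels, n_roi = n_roi)
  eff <- cohort_effect_lookup(spec, unique(atlas$meta$lobe))
  lf <- atlas_lobe_field(atlas)
  gm <- template$truth$gm_mask
  # raw-intensity SD of the detrended noise-free GM signal: residual of the
  # laminar profile (+ imposed trends) on [1, curvature, thickness], plus
  # voxel noise
  base <- phantom$intensity_profile(template$truth$depth$data[gm]) +
    phantom$curvature_coeff * template$truth$curvature$data[gm] +
    phantom$thickness_coeff * template$truth$thickness$data[gm]
  X <- cbind(1, template$truth$curvature$data[gm],
             template$truth$thickness$data[gm])
  res <- tryCatch(lm.fit(X, base)$residuals, error = function(e) base - mean(base))
  z_unit <- sqrt(var(res) + phantom$noise_sd^2)

  local_seed(spec$seed, {
    cov <- cohort_covariates(spec)
    intercepts <- rnorm(nrow(cov), 0, spec$random_intercept_sd)
    seeds <- (spec$seed + seq_len(nrow(cov)) * 9973L) %% 2147483647L
    participants <- vector("list", nrow(cov))
    names(participants) <- cov$participant_id
    for (i in seq_len(nrow(cov))) {
      off <- array(0, dim(gm))
      gl <- eff[cov$group[i], ]
      vox_lobe <- lf$lobe_index
      for (li in seq_along(lf$lobes)) {
        delta <- gl[lf$lobes[li]]
        if (!is.na(delta) && delta != 0)
          off[!is.na(vox_lobe) & vox_lobe == li] <- delta * z_unit
      }
      off <- off + intercepts[i] * z_unit
      pspec <- phantom
      pspec$seed <- seeds[i]
      participants[[i]] <- make_phantom(pspec, offset = off,
                                        group_offsets = gl)
    }
    list(participants = participants, covariates = cov, atlas = atlas,
         z_unit_sd = z_unit)
  })
}
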