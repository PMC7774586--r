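# Per-participant intensity modelling and ROI aggregation: detrend GM
# intensity for curvature and thickness, z-score the residuals, select ROI
# voxels by probability quantile and mid-depth window, and build the
# long-format feature table used by the group statistics.

#' Detrend and z-score GM intensity
#'
#' Ordinary least squares of GM intensity on an intercept, local curvature
#' and local thickness; the residuals (orthogonal to both regressors by
#' construction) are z-scored by their own mean and SD, so the resulting map
#' is centred on 0 with unit SD over GM: the individual T1-w average.
#'
#' @param intensity a `volume_grid` of (prepared) T1-w-like intensity.
#' @param curvature,thickness geometry `volume_grid`s from
#'   [local_curvature()] and [local_thickness()].
#' @param gm_mask logical array of GM voxels.
#' @return An object of class `z_scored_gm`: list with `zvol` (a
#'   `volume_grid`, `NA` outside GM), `coefficients` (intercept, curvature
#'   and thickness slopes), `gm_mean`, `gm_sd` (residual moments before
#'   scaling) and `n_gm`.
#' @export
detrend_gm <- function(intensity, curvature, thickness, gm_mask) {
  stopifnot(inherits(intensity, "volume_grid"))
  gm <- as.logical(gm_mask)
  y <- intensity$data[gm]
  X <- cbind(intercept = 1, curvature = curvature$data[gm],
             thickness = thickness$data[gm])
  if (nrow(X) < 3) stop("need at least 3 GM voxels to detrend")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite intensity or regressors inside GM")
  sv <- svd(scale(X[, 2:3], center = TRUE, scale = FALSE))$d
  cond <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > 1e8)
    stop(sprintf(
      "collinear curvature/thickness regressors (condition number %.3g)",
      cond))
  fit <- lm.fit(X, y)
  res <- fit$residuals
  s <- sd(res)
  if (!is.finite(s) || s < 1e-12)
    stop("constant residuals (SD = 0): intensity is an exact function of the regressors")
  m <- mean(res)
  z <- array(NA_real_, dim(intensity$data))
  z[gm] <- (res - m) / s
  structure(list(
    zvol = volume_grid(z, intensity$spacing, intensity$affine,
                       intensity$space),
    coefficients = setNames(fit$coefficients,
                            c("intercept", "curvature", "thickness")),
    gm_mean = m, gm_sd = s, n_gm = sum(gm)
  ), class = "z_scored_gm")
}

#' @export
print.z_scored_gm <- function(x, ...) {
  cat(sprintf(
    "<z_scored_gm> %d GM voxels; slopes: curvature %.4g, thickness %.4g\n",
    x$n_gm, x$coefficients["curvature"], x$coefficients["thickness"]))
  invisible(x)
}

#' Select ROI voxels by probability quantile and depth window
#'
#' Implements the mid-depth probabilistic selection rule: GM voxels whose
#' ROI probability is strictly greater than the 25% quantile of the ROI's
#' strictly positive probabilities (linear-interpolation quantile, type 7)
#' and whose cortical depth lies within the window (endpoints inclusive).
#'
#' @param roi_prob `volume_grid` of the ROI probability field.
#' @param depthmap a `depth_map`.
#' @param gm_mask logical GM array.
#' @param prob_quantile quantile of the positive-probability support used as
#'   the strict threshold. Default 0.25.
#' @param depth_window inclusive depth interval. Default `c(0.4, 0.6)`.
#' @return Integer vector of selected voxel indices (column-major).
#' @export
select_roi_voxels <- function(roi_prob, depthmap, gm_mask,
                              prob_quantile = 0.25,
                              depth_window = c(0.4, 0.6)) {
  p <- roi_prob$data
  pos <- p[p > 0 & !is.na(p)]
  if (!length(pos)) stop("ROI has no positive-probability support")
  thr <- quantile(pos, prob_quantile, type = 7, names = FALSE)
  dep <- depthmap$data
  sel <- which(as.logical(gm_mask) & !is.na(dep) & p > thr &
                 dep >= depth_window[1] & dep <= depth_window[2])
  sel
}

#' Aggregate features over a voxel selection
#'
#' @param z a `z_scored_gm` (or a `volume_grid` of z values).
#' @param thickness thickness `volume_grid`.
#' @param selection integer voxel indices from [select_roi_voxels()].
#' @return List with `mean_z_gm`, `mean_thickness_mm`, `n_voxels`; means are
#'   `NA` for an empty selection.
#' @export
aggregate_roi <- function(z, thickness, selection) {
  zv <- if (inherits(z, "z_scored_gm")) z$zvol$data else z$data
  if (!length(selection))
    return(list(mean_z_gm = NA_real_, mean_thickness_mm = NA_real_,
                n_voxels = 0L))
  list(mean_z_gm = mean(zv[selection]),
       mean_thickness_mm = mean(thickness$data[selection]),
       n_voxels = length(selection))
}

#' Build the long-format participant x ROI feature table
#'
#' Applies the selection and aggregation rules for every participant and
#' atlas ROI and joins lobe/hemisphere metadata and participant covariates.
#' Row order is deterministic: participant, then ROI (atlas order). Rows
#' whose selection is empty carry missing feature values; their count is
#' reported in a message and they are excluded from modelling downstream.
#'
#' @param participants named list (names = participant ids); each element a
#'   list with `z` (a `z_scored_gm`), `depth` (a `depth_map`), `thickness`
#'   (a `volume_grid`) and `gm_mask`.
#' @param atlas a `prob_atlas` on the participants' grid.
#' @param covariates data.frame with `participant_id`, `group`, `age`,
#'   `gender`; one row per participant.
#' @param prob_quantile,depth_window selection parameters, see
#'   [select_roi_voxels()].
#' @return data.frame with one row per participant x ROI: participant_id,
#'   group, age, gender, roi_id, hemisphere, lobe, mean_z_gm,
#'   mean_thickness_mm, n_voxels_selected.
#' @export
build_feature_table <- function(participants, atlas, covariates,
                                prob_quantile = 0.25,
                                depth_window = c(0.4, 0.6)) {
  stopifnot(inherits(atlas, "prob_atlas"))
  ids <- sort(names(participants))
  missing_cov <- setdiff(ids, covariates$participant_id)
  if (length(missing_cov))
    stop("participants missing from covariates: ",
         paste(missing_cov, collapse = ", "))
  rows <- vector("list", length(ids) * nrow(atlas$meta))
  r <- 0L
  for (id in ids) {
    pp <- participants[[id]]
    cv <- covariates[covariates$participant_id == id, , drop = FALSE][1, ]
    for (k in seq_len(nrow(atlas$meta))) {
      roi <- atlas$meta$roi_id[k]
      sel <- select_roi_voxels(atlas$prob[[roi]], pp$depth, pp$gm_mask,
                               prob_quantile, depth_window)
      ag <- aggregate_roi(pp$z, pp$thickness, sel)
      r <- r + 1L
      rows[[r]] <- data.frame(
        participant_id = id, group = cv$group, age = cv$age,
        gender = cv$gender, roi_id = roi,
        hemisphere = atlas$meta$hemisphere[k], lobe = atlas$meta$lobe[k],
        mean_z_gm = ag$mean_z_gm, mean_thickness_mm = ag$mean_thickness_mm,
        n_voxels_selected = ag$n_voxels, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  n_empty <- sum(tab$n_voxels_selected == 0)
  if (n_empty > 0)
    message("build_feature_table: ", n_empty,
            " participant x ROI row(s) with empty selection (features NA)")
  rownames(tab) <- NULL
  tab
}
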