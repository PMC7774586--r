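# Probabilistic ROI atlases: per-ROI probability volumes in a reference
# space plus tabular ROI metadata (name, hemisphere, lobe).

#' Construct a probabilistic atlas
#'
#' @param prob named list of `volume_grid`s, one probability field per ROI,
#'   values in \[0,1\]; names are ROI ids.
#' @param meta data.frame with columns `roi_id`, `name`, `hemisphere`
#'   ("left"/"right"), `lobe` ("frontal", "parietal", "temporal",
#'   "occipital"); exactly one row per ROI in `prob`.
#' @return An object of class `prob_atlas`.
#' @export
prob_atlas <- function(prob, meta) {
  stopifnot(is.list(prob), length(prob) > 0, !is.null(names(prob)))
  need <- c("roi_id", "name", "hemisphere", "lobe")
  if (!all(need %in% names(meta)))
    stop("meta must have columns: ", paste(need, collapse = ", "))
  if (!setequal(meta$roi_id, names(prob)))
    stop("meta roi_id set does not match probability volume names")
  if (anyDuplicated(meta$roi_id)) stop("duplicate roi_id in meta")
  if (!all(meta$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (!all(meta$lobe %in% c("frontal", "parietal", "temporal", "occipital")))
    stop("lobe must be one of frontal, parietal, temporal, occipital")
  for (id in names(prob)) {
    p <- prob[[id]]$data
    if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
      stop("probabilities out of [0,1] for ROI ", id)
  }
  meta <- meta[match(names(prob), meta$roi_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(prob = prob, meta = meta), class = "prob_atlas")
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> %d ROIs (%s)\n", length(x$prob),
              paste(sprintf("%s: %d", names(table(x$meta$lobe)),
                            as.integer(table(x$meta$lobe))), collapse = ", ")))
  invisible(x)
}

#' 70-ROI Desikan-Killiany metadata
#'
#' Tabular metadata for the 70-region gyral parcellation used for ROI
#' aggregation: 35 labels per hemisphere with the package's lobe assignment
#' (frontal, parietal, temporal, occipital).
#'
#' @return data.frame with columns `roi_id`, `name`, `hemisphere`, `lobe`.
#' @examples
#' nrow(dk_atlas_meta())
#' @export
dk_atlas_meta <- function() {
  read.delim(system.file("extdata", "dk_rois.tsv", package = "laminargm"),
             stringsAsFactors = FALSE)
}

#' Synthetic probabilistic atlas for a phantom grid
#'
#' Tiles the phantom's x-y extent into `n_lobe_bands x n_per_band` regions
#' (x bands mapping to the four lobes, the y sign to hemisphere) and builds a
#' smooth Gaussian probability bump per tile, emulating a probabilistic
#' parcellation with per-ROI probability ranges. Intended for slab/folded
#' phantoms in pipeline recovery experiments.
#'
#' @param grid a `volume_grid` (typically the phantom labels) defining the
#'   space.
#' @param n_roi total number of ROIs; must be a multiple of 8 (4 lobes x 2
#'   hemispheres) for a balanced design. Default 16.
#' @param sigma_frac bump width as a fraction of the tile size.
#' @param overlap if `FALSE` (default) each bump is truncated at its tile
#'   boundary, giving a crisp parcellation whose ROI supports partition the
#'   grid (the configuration used for effect-recovery experiments); if
#'   `TRUE` the bumps extend across tiles, emulating overlapping
#'   probabilistic ROIs.
#' @return A `prob_atlas` on the phantom grid.
#' @export
make_phantom_atlas <- function(grid, n_roi = 16, sigma_frac = 0.45,
                               overlap = FALSE) {
  stopifnot(inherits(grid, "volume_grid"))
  if (n_roi %% 8 != 0) stop("n_roi must be a multiple of 8")
  per_hemi <- n_roi / 2          # tiles per hemisphere (y half)
  nxb <- 4L                      # one x band per lobe
  nyb <- as.integer(per_hemi / nxb)
  w <- grid_world(grid)
  xr <- range(w$x); yr <- range(w$y)
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  xw <- diff(xr) / nxb
  yw <- diff(yr) / (2 * nyb)
  prob <- list()
  meta <- NULL
  for (hemi_i in 1:2) {
    hemi <- c("left", "right")[hemi_i]
    for (bx in seq_len(nxb)) for (by in seq_len(nyb)) {
      cx <- xr[1] + (bx - 0.5) * xw
      cy <- yr[1] + ((hemi_i - 1) * nyb + by - 0.5) * yw
      p <- exp(-(((w$x - cx) / (sigma_frac * xw))^2 +
                   ((w$y - cy) / (sigma_frac * yw))^2) / 2)
      p[p < 0.05] <- 0
      if (!overlap)
        p[abs(w$x - cx) > xw / 2 | abs(w$y - cy) > yw / 2] <- 0
      id <- sprintf("%s_%s_%d", substr(hemi, 1, 1), lobes[bx], by)
      prob[[id]] <- volume_grid(p, grid$spacing, grid$affine, grid$space)
      meta <- rbind(meta, data.frame(roi_id = id,
                                     name = sprintf("%s %s tile %d",
                                                    hemi, lobes[bx], by),
                                     hemisphere = hemi, lobe = lobes[bx],
                                     stringsAsFactors = FALSE))
    }
  }
  prob_atlas(prob, meta)
}

#' Resample an atlas into subject space by nearest neighbour
#'
#' Looks every subject-grid voxel centre up in the reference grid through the
#' given reference-to-subject affine and takes the nearest reference voxel's
#' value, leaving probability values unchanged (no blending).
#'
#' @param atlas a `prob_atlas` in reference space.
#' @param affine_ref_to_subject 4x4 world-to-world affine mapping reference
#'   coordinates to subject coordinates; must be invertible.
#' @param target_grid a `volume_grid` defining the subject grid.
#' @return A `prob_atlas` on the subject grid.
#' @export
atlas_to_subject <- function(atlas, affine_ref_to_subject, target_grid) {
  stopifnot(inherits(atlas, "prob_atlas"), inherits(target_grid, "volume_grid"))
  A <- as.matrix(affine_ref_to_subject)
  if (abs(det(A)) < 1e-12) stop("singular reference-to-subject affine")
  Ainv <- solve(A)
  d <- dim(target_grid$data)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  w_sub <- cbind(ijk, 1) %*% t(target_grid$affine)
  w_ref <- w_sub %*% t(Ainv)
  out <- list()
  for (id in names(atlas$prob)) {
    ref <- atlas$prob[[id]]
    iref <- w_ref %*% t(solve(ref$affine))
    ii <- round(iref[, 1]) + 1; jj <- round(iref[, 2]) + 1
    kk <- round(iref[, 3]) + 1
    dr <- dim(ref$data)
    ok <- ii >= 1 & ii <= dr[1] & jj >= 1 & jj <= dr[2] & kk >= 1 & kk <= dr[3]
    vals <- numeric(nrow(ijk))
    vals[ok] <- ref$data[cbind(ii[ok], jj[ok], kk[ok])]
    out[[id]] <- volume_grid(array(vals, d), target_grid$spacing,
                             target_grid$affine, target_grid$space)
  }
  prob_atlas(out, atlas$meta)
}

# voxelwise lobe assignment by maximum ROI probability; NA where all zero
atlas_lobe_field <- function(atlas) {
  d <- dim(atlas$prob[[1]]$data)
  best <- array(0, d)
  lobe_i <- array(NA_integer_, d)
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  for (id in names(atlas$prob)) {
    p <- atlas$prob[[id]]$data
    li <- match(atlas$meta$lobe[atlas$meta$roi_id == id], lobes)
    upd <- p > best
    best[upd] <- p[upd]
    lobe_i[upd] <- li
  }
  list(lobe_index = lobe_i, lobes = lobes)
}
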