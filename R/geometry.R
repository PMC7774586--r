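# Laminar geometry: spacing-aware interface distance fields, equidistant and
# equi-volume cortical depth, mean curvature of the mid-surface level set,
# and cortical thickness.
#
# Interface convention: the tissue interface is localized at the face between
# differing labels. Unsigned distances are measured from voxel centres to the
# set of interface face midpoints, rasterized on a 2x supersampled grid so
# that face midpoints fall on grid sites; a GM voxel touching WM is exactly
# half a voxel from the WM-GM interface.
#
# Noise control: binary labels quantize the interfaces at half-voxel scale.
# Rather than using the raw per-voxel distances, the signed interface
# distances are combined into two global fields that are smooth by
# construction -- the depth fraction rho = phi_wm / (phi_wm + phi_csf)
# (a linear ramp across the ribbon) and the thickness tau = phi_wm + phi_csf
# (constant along a traverse) -- which are Gaussian-smoothed and re-expanded
# into d_wm = rho * tau, d_csf = (1 - rho) * tau. The smoothing bias of rho
# in curved cortex (proportional to sigma^2 H / tau) is removed using the
# measured mean curvature.

# Midpoints of faces between GM voxels and voxels of `other_code`, marked on
# the 2x supersampled grid (fine index 2i-1 for voxel centre i, 2i for the
# face between voxels i and i+1).
face_site_mask <- function(lab, other_code) {
  d <- dim(lab)
  df <- 2L * d - 1L
  m <- array(FALSE, df)
  gm <- lab == 2L
  oth <- lab == other_code
  for (ax in 1:3) {
    n <- d[ax]
    lo <- lapply(d, seq_len); hi <- lo
    lo[[ax]] <- seq_len(n - 1L)        # voxel i
    hi[[ax]] <- 2:n                    # voxel i+1
    A_gm <- gm[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    B_gm <- gm[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
    A_ot <- oth[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    B_ot <- oth[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
    face <- (A_gm & B_ot) | (A_ot & B_gm)
    if (!any(face)) next
    w <- which(face, arr.ind = TRUE)
    fine <- 2L * w - 1L                # centre of voxel i on the fine grid
    fine[, ax] <- fine[, ax] + 1L      # shift to the shared face midpoint
    m[fine] <- TRUE
  }
  m
}

# Unsigned distance (mm) from every coarse voxel centre to the GM/other
# interface faces.
interface_edt <- function(lab, other_code, spacing) {
  m <- face_site_mask(lab, other_code)
  fine <- edt_mm(m, spacing / 2)
  d <- dim(lab)
  fine[seq(1L, 2L * d[1] - 1L, 2L), seq(1L, 2L * d[2] - 1L, 2L),
       seq(1L, 2L * d[3] - 1L, 2L)]
}

# Core laminar field computation shared by interface_distances and
# local_curvature. Returns arrays on the full grid.
laminar_fields <- function(labels, sigma_vox = 1, sigma_curv_vox = 1.5) {
  stopifnot(inherits(labels, "volume_grid"))
  lab <- labels$data
  gm <- lab == 2L
  if (!any(gm)) stop("no GM voxels in segmentation")
  wm <- lab == 3L
  csf <- lab == 1L
  adj_gm <- function(m) {
    a <- array(FALSE, dim(lab))
    for (ax in 1:3) for (s in c(-1L, 1L)) a <- a | (shift_axis(m, ax, s) & gm)
    any(a)
  }
  if (!any(wm) || !adj_gm(wm))
    stop("missing WM-GM interface: no WM voxels adjacent to GM")
  if (!any(csf) || !adj_gm(csf))
    stop("missing GM-CSF interface: no CSF voxels adjacent to GM")
  h <- labels$spacing
  # signed distances: WM interface positive on the GM/CSF side, CSF interface
  # positive on the GM/WM side
  phi_w <- interface_edt(lab, 3L, h) * ifelse(wm, -1, 1)
  phi_c <- interface_edt(lab, 1L, h) * ifelse(csf | lab == 0L, -1, 1)
  tau_raw <- phi_w + phi_c
  tau_safe <- sign(tau_raw + (tau_raw == 0)) * pmax(abs(tau_raw), 0.3 * mean(h))
  rho_raw <- phi_w / tau_safe
  tau <- gaussian_smooth3(tau_raw, sigma_vox)
  rho <- gaussian_smooth3(rho_raw, sigma_vox)

  # mean curvature of the mid-surface level set psi = (rho - 0.5) * tau
  psi <- (rho - 0.5) * tau
  gx <- axis_diff(psi, 1, h[1]); gy <- axis_diff(psi, 2, h[2])
  gz <- axis_diff(psi, 3, h[3])
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  ok <- gn > 0.3
  nxa <- ifelse(ok, gx / gn, NA_real_)
  nya <- ifelse(ok, gy / gn, NA_real_)
  nza <- ifelse(ok, gz / gn, NA_real_)
  H <- 0.5 * (axis_diff(nxa, 1, h[1]) + axis_diff(nya, 2, h[2]) +
                axis_diff(nza, 3, h[3]))
  # invalidate voxels whose smoothing/stencil support is truncated by the
  # grid border, then impute from valid neighbours before re-smoothing
  mrg <- as.integer(ceiling(3 * sigma_vox) + 3L)
  d <- dim(lab)
  edge <- array(FALSE, d)
  if (all(d > 2L * mrg)) {
    keep <- lapply(d, function(n) (mrg + 1L):(n - mrg))
    edge[, , ] <- TRUE
    edge[keep[[1]], keep[[2]], keep[[3]]] <- FALSE
  }
  H[edge | !ok | !is.finite(H)] <- NA_real_
  n_imputed <- sum(is.na(H) & gm)
  H <- fill_from_neighbours(H)
  H[is.na(H)] <- 0
  if (sigma_curv_vox > 0) H <- gaussian_smooth3(H, sigma_curv_vox)

  # curvature-bias correction of the smoothed depth fraction
  sg <- sigma_vox * mean(h)
  rho_c <- rho - sg^2 * H / pmax(abs(tau), 0.5)
  d_wm <- pmax(rho_c * tau, 0)
  d_csf <- pmax((1 - rho_c) * tau, 0)
  list(d_wm = d_wm, d_csf = d_csf, H = H, gm = gm,
       n_imputed = n_imputed)
}

#' Distances to the WM-GM and GM-CSF interfaces
#'
#' Computes, for every grey-matter voxel, the distance in mm to the
#' white-matter interface and to the CSF interface, using an exact
#' spacing-aware Euclidean distance transform to the interface faces
#' (half-voxel face-offset convention) with anti-aliasing of the binary
#' label staircase (see the package vignette for the field construction).
#'
#' @param labels a `volume_grid` of tissue codes (see [label_codes()]).
#' @param sigma_vox anti-aliasing smoothing SD in voxels.
#' @return A list with `volume_grid` elements `d_wm` and `d_csf`, defined
#'   (finite) on GM voxels and `NA` elsewhere, plus `gm_mask`. The full
#'   field set is attached as attribute `"fields"` for reuse by
#'   [local_curvature()].
#' @export
interface_distances <- function(labels, sigma_vox = 1) {
  fl <- laminar_fields(labels, sigma_vox = sigma_vox)
  dw <- fl$d_wm; dc <- fl$d_csf
  dw[!fl$gm] <- NA_real_; dc[!fl$gm] <- NA_real_
  mk <- function(a) volume_grid(a, labels$spacing, labels$affine, labels$space)
  out <- list(d_wm = mk(dw), d_csf = mk(dc), gm_mask = fl$gm)
  attr(out, "fields") <- fl
  out
}

new_depth_map <- function(vg, method) {
  structure(vg, class = c("depth_map", "volume_grid"), method = method)
}

#' Equidistant cortical depth
#'
#' The naive depth coordinate `d_wm / (d_wm + d_csf)`: 0 at the WM-GM
#' interface, 1 at the GM-CSF interface. Biased toward the CSF side in
#' curved cortex; see [equivolume_depth()] for the folding-compensated map.
#'
#' @param d_wm,d_csf interface distance volumes from [interface_distances()].
#' @return A `depth_map` (a `volume_grid` with depth in \[0,1\] on GM).
#' @export
equidistant_depth <- function(d_wm, d_csf) {
  dw <- d_wm$data; dc <- d_csf$data
  tot <- dw + dc
  bad <- which(is.finite(tot) & tot == 0)
  if (length(bad))
    stop("inconsistent segmentation: ", length(bad),
         " GM voxel(s) at zero distance from both interfaces")
  out <- d_wm
  out$data <- pmin(pmax(dw / tot, 0), 1)
  new_depth_map(out, "equidistant")
}

#' Equi-volume cortical depth
#'
#' Converts the equidistant fraction into a local volume fraction using a
#' frustum model of the cortical traverse: the bounding WM-side and CSF-side
#' surface areas are inferred from the local mean curvature `H` and the
#' interface distances (area proportional to `(1 -/+ H d)^2`), and the
#' returned depth is the fraction of the frustum volume below the voxel,
#' `alpha = (A_csf - sqrt((1 - rho) A_csf^2 + rho A_wm^2)) / (A_csf - A_wm)`.
#' With equal areas (flat cortex) the map reduces to the equidistant
#' fraction. Values are clamped to \[0,1\]; clamping by more than `warn_tol`
#' triggers a warning as a segmentation-quality signal.
#'
#' @param d_wm,d_csf interface distance volumes from [interface_distances()].
#' @param curvature mean-curvature `volume_grid` (1/mm) from
#'   [local_curvature()].
#' @param warn_tol out-of-range magnitude tolerated before warning.
#' @return A `depth_map` with method `"equivolume"`.
#' @export
equivolume_depth <- function(d_wm, d_csf, curvature, warn_tol = 0.05) {
  dw <- d_wm$data; dc <- d_csf$data; H <- curvature$data
  gm <- is.finite(dw) & is.finite(dc)
  if (any(gm & !is.finite(H)))
    stop("non-finite curvature inside GM (",
         sum(gm & !is.finite(H)), " voxels)")
  tot <- dw + dc
  rho <- dw / tot
  fw <- pmax(1 - H * dw, 0.1)   # WM-side radius factor
  fc <- pmax(1 + H * dc, 0.1)   # CSF-side radius factor
  aw <- fw^2; ac <- fc^2
  denom <- aw - ac
  flat <- is.finite(denom) & abs(denom) < 1e-9
  s <- sqrt(pmax((1 - rho) * ac^2 + rho * aw^2, 0))
  alpha <- (-ac + s) / denom
  alpha[flat] <- rho[flat]
  fin <- alpha[is.finite(alpha)]
  if (length(fin)) {
    over <- max(0, max(fin - 1), max(-fin))
    if (over > warn_tol)
      warning(sprintf(
        "equi-volume depth clamped by up to %.3f; check segmentation quality",
        over))
  }
  out <- d_wm
  out$data <- pmin(pmax(alpha, 0), 1)
  new_depth_map(out, "equivolume")
}

#' Local mean curvature of the cortical mid-surface
#'
#' Evaluates the mean curvature `H = 0.5 * div(grad(psi)/|grad(psi)|)` of
#' the signed distance field `psi` to the 0.5 equidistant surface, built
#' from the Gaussian pre-smoothed interface distance fields (default sigma
#' of one voxel) and regularized by a second smoothing pass on the curvature
#' field itself. Positive where the surface bulges toward CSF (gyral
#' crown), negative in sulcal fundi; `1/r` on a sphere of radius `r`.
#' Voxels where the gradient vanishes or the stencil is truncated by the
#' grid border are imputed from their nearest valid neighbours and counted
#' in a message.
#'
#' @param labels tissue label `volume_grid`.
#' @param distances optional precomputed [interface_distances()] result
#'   (reused to avoid recomputation).
#' @param sigma_vox pre-smoothing SD of the level-set field (voxels).
#' @param sigma_curv_vox smoothing SD applied to the curvature field
#'   (voxels).
#' @return A mean-curvature `volume_grid` (1/mm) defined on GM.
#' @export
local_curvature <- function(labels, distances = NULL, sigma_vox = 1,
                            sigma_curv_vox = 1.5) {
  fl <- if (!is.null(distances) && !is.null(attr(distances, "fields")))
    attr(distances, "fields")
  else laminar_fields(labels, sigma_vox = sigma_vox,
                      sigma_curv_vox = sigma_curv_vox)
  if (fl$n_imputed > 0)
    message("local_curvature: imputed ", fl$n_imputed,
            " GM voxel(s) from nearest valid neighbours")
  H <- fl$H
  H[!fl$gm] <- NA_real_
  volume_grid(H, labels$spacing, labels$affine, labels$space)
}

#' Local cortical thickness
#'
#' Thickness at every GM voxel as the sum of the distances to the two
#' interfaces, `d_wm + d_csf` (mm); constant along a cortical traverse up to
#' discretization.
#'
#' @param d_wm,d_csf interface distance volumes from [interface_distances()].
#' @return A thickness `volume_grid` (mm), positive on GM.
#' @export
local_thickness <- function(d_wm, d_csf) {
  out <- d_wm
  out$data <- d_wm$data + d_csf$data
  out
}

#' Full laminar geometry from a segmentation
#'
#' Convenience wrapper running [interface_distances()], [local_curvature()],
#' [local_thickness()], [equidistant_depth()] and [equivolume_depth()] with
#' shared intermediate fields.
#'
#' @param labels tissue label `volume_grid`.
#' @param sigma_vox level-set pre-smoothing SD (voxels).
#' @param sigma_curv_vox curvature-field smoothing SD (voxels).
#' @return List with `depth` (equi-volume `depth_map`), `depth_equidistant`,
#'   `curvature`, `thickness`, `distances`.
#' @export
laminar_geometry <- function(labels, sigma_vox = 1, sigma_curv_vox = 1.5) {
  dst <- interface_distances(labels, sigma_vox = sigma_vox)
  curv <- local_curvature(labels, distances = dst)
  thick <- local_thickness(dst$d_wm, dst$d_csf)
  eqd <- equidistant_depth(dst$d_wm, dst$d_csf)
  eqv <- equivolume_depth(dst$d_wm, dst$d_csf, curv)
  list(depth = eqv, depth_equidistant = eqd, curvature = curv,
       thickness = thick, distances = dst)
}
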