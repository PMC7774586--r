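# Iso-depth surface extraction via tetrahedral decomposition of the voxel
# grid (marching tetrahedra: each cell split into six tetrahedra around the
# main diagonal, linear interpolation along crossed edges). Produces a
# triangle mesh in world coordinates; watertight on closed phantoms.

# corner offsets, bit order (x, y, z)
.mt_corners <- matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
                        0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
                      ncol = 3, byrow = TRUE)
# six tetrahedra around the 0-6 diagonal (1-based corner ids)
.mt_tets <- matrix(c(1, 2, 3, 7,  1, 3, 4, 7,  1, 4, 8, 7,
                     1, 8, 5, 7,  1, 5, 6, 7,  1, 6, 2, 7),
                   ncol = 4, byrow = TRUE)

#' Extract an iso-depth surface mesh
#'
#' Meshes the surface at a given cortical depth level from a depth map. The
#' depth field is extended outside GM using the tissue labels (below the
#' level on the WM side, above it on the CSF side) so that the iso-surface
#' closes across the interfaces. Optionally samples a scalar volume onto the
#' vertices by trilinear interpolation.
#'
#' @param depthmap a `depth_map` from [equivolume_depth()] or
#'   [equidistant_depth()].
#' @param labels tissue label `volume_grid` matching the depth grid.
#' @param level iso level in (0,1); 0 and 1 are accepted and mesh the
#'   WM-GM / GM-CSF interfaces.
#' @param scalar optional `volume_grid` sampled at the vertices.
#' @return An object of class `surface_mesh`: list with `vertices` (n x 3 mm,
#'   world space), `triangles` (m x 3 vertex indices), and optionally
#'   `scalar_per_vertex`.
#' @export
extract_surface <- function(depthmap, labels, level = 0.5, scalar = NULL) {
  stopifnot(inherits(depthmap, "volume_grid"), inherits(labels, "volume_grid"))
  if (level < 0 || level > 1) stop("level must lie in [0, 1]")
  f <- depthmap$data
  lab <- labels$data
  f[lab == 3L] <- -0.25
  f[lab == 1L] <- 1.25
  f[lab == 0L] <- NA_real_   # background: cells touching it are not meshed
  f[is.na(f) & lab != 0L] <- 1.25
  lv <- if (level <= 0) -0.05 else if (level >= 1) 1.05 else level
  f[!is.na(f) & f == lv] <- lv + 1e-9
  d <- dim(f)
  sub <- function(dx, dy, dz)
    f[(1 + dx):(d[1] - 1 + dx), (1 + dy):(d[2] - 1 + dy),
      (1 + dz):(d[3] - 1 + dz)]
  cv <- vector("list", 8)
  for (c8 in 1:8)
    cv[[c8]] <- sub(.mt_corners[c8, 1], .mt_corners[c8, 2], .mt_corners[c8, 3])
  cmin <- Reduce(pmin, cv); cmax <- Reduce(pmax, cv)
  act <- which(!is.na(cmin) & !is.na(cmax) & cmin < lv & cmax > lv)
  if (!length(act)) stop("empty iso-surface at level ", level)
  dd <- d - 1L
  ai <- arrayInd(act, dd)
  vals <- vapply(cv, function(a) a[act], numeric(length(act)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)

  tri <- vector("list", length(act))
  n_tri <- 0L
  out <- list()
  for (q in seq_along(act)) {
    base <- ai[q, ] - 1L   # 0-based cube origin
    v8 <- vals[q, ]
    for (t in 1:6) {
      ids <- .mt_tets[t, ]
      tv <- v8[ids]
      inside <- tv > lv
      ni <- sum(inside)
      if (ni == 0L || ni == 4L) next
      P <- .mt_corners[ids, , drop = FALSE]
      ip <- function(a, b) {
        s <- (lv - tv[a]) / (tv[b] - tv[a])
        P[a, ] + s * (P[b, ] - P[a, ])
      }
      w <- which(inside); o <- which(!inside)
      if (ni == 1L || ni == 3L) {
        a <- if (ni == 1L) w else o
        rest <- setdiff(1:4, a)
        out[[length(out) + 1L]] <-
          rbind(base + ip(a, rest[1]), base + ip(a, rest[2]),
                base + ip(a, rest[3]))
      } else {
        # two inside: quad split into two triangles
        e1 <- ip(w[1], o[1]); e2 <- ip(w[1], o[2])
        e3 <- ip(w[2], o[1]); e4 <- ip(w[2], o[2])
        out[[length(out) + 1L]] <- rbind(base + e1, base + e2, base + e3)
        out[[length(out) + 1L]] <- rbind(base + e2, base + e4, base + e3)
      }
    }
  }
  if (!length(out)) stop("empty iso-surface at level ", level)
  V <- do.call(rbind, out)              # voxel coordinates, 0-based
  key <- paste(round(V[, 1], 6), round(V[, 2], 6), round(V[, 3], 6))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts_vox <- V[uk, , drop = FALSE]
  tris <- matrix(vid, ncol = 3, byrow = TRUE)
  W <- cbind(verts_vox, 1) %*% t(depthmap$affine)
  mesh <- list(vertices = W[, 1:3, drop = FALSE], triangles = tris)
  if (!is.null(scalar)) {
    mesh$scalar_per_vertex <- trilinear(scalar$data, verts_vox[, 1] + 1,
                                        verts_vox[, 2] + 1, verts_vox[, 3] + 1)
  }
  class(mesh) <- "surface_mesh"
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  has_sc <- !is.null(mesh$scalar_per_vertex)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               if (has_sc) "property float scalar",
               paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vm <- mesh$vertices
  if (has_sc) vm <- cbind(vm, mesh$scalar_per_vertex)
  writeLines(apply(format(vm, trim = TRUE, digits = 7), 1, paste,
                   collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                   mesh$triangles[, 3] - 1), con)
  invisible(path)
}
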