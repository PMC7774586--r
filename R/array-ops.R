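# Internal 3D array numerics: shifts, finite differences, separable Gaussian
# smoothing, trilinear interpolation and a local RNG scope. All distances in
# mm are derived from the voxel spacing, never from index counts alone.

# Evaluate an expression with a temporary RNG state seeded at `seed`,
# restoring the caller's state afterwards. seed = NULL runs unseeded.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shift an array by one voxel along `axis` (+1 or -1 steps), replicating the
# edge plane (clamp-to-edge).
shift_axis <- function(a, axis, step) {
  d <- dim(a)
  idx <- lapply(seq_len(3), function(k) seq_len(d[k]))
  src <- idx[[axis]] - step
  src[src < 1] <- 1L
  src[src > d[axis]] <- d[axis]
  idx[[axis]] <- src
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Central finite difference along `axis` with grid step h (one-sided at the
# array boundary, where the central stencil would leave the grid).
axis_diff <- function(a, axis, h) {
  d <- dim(a)
  fwd <- shift_axis(a, axis, -1L)  # value at i+1
  bwd <- shift_axis(a, axis, 1L)   # value at i-1
  g <- (fwd - bwd) / (2 * h)
  # boundary planes: one-sided difference
  idx <- lapply(seq_len(3), function(k) seq_len(d[k]))
  lo <- idx; lo[[axis]] <- 1L
  hi <- idx; hi[[axis]] <- d[axis]
  g[lo[[1]], lo[[2]], lo[[3]]] <-
    (fwd - a)[lo[[1]], lo[[2]], lo[[3]]] / h
  g[hi[[1]], hi[[2]], hi[[3]]] <-
    (a - bwd)[hi[[1]], hi[[2]], hi[[3]]] / h
  g
}

# Normalized truncated Gaussian kernel matrix (n x n) for 1D smoothing with
# standard deviation sigma_vox in voxel units; rows renormalized at the edges.
gauss_kernel_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    w <- exp(-((a - b)^2) / (2 * sigma_vox^2))
    w * (abs(a - b) <= r)
  })
  K / rowSums(K)
}

# Separable Gaussian smoothing of a 3D array; sigma_vox per axis (voxels).
gaussian_smooth3 <- function(a, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- gauss_kernel_matrix(d[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    m <- K %*% m
    dim(m) <- dm
    a <- aperm(m, order(perm))
  }
  a
}

# Trilinear interpolation of 3D array `a` at fractional 1-based voxel
# coordinates (vectors ix, iy, iz of equal length), clamped to the grid.
trilinear <- function(a, ix, iy, iz) {
  d <- dim(a)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ix <- clamp(ix, 1, d[1]); iy <- clamp(iy, 1, d[2]); iz <- clamp(iz, 1, d[3])
  x0 <- clamp(floor(ix), 1, d[1] - 1L); x1 <- x0 + 1
  y0 <- clamp(floor(iy), 1, d[2] - 1L); y1 <- y0 + 1
  z0 <- clamp(floor(iz), 1, d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1) { x0 <- x1 <- rep(1, length(ix)) }
  if (d[2] == 1) { y0 <- y1 <- rep(1, length(iy)) }
  if (d[3] == 1) { z0 <- z1 <- rep(1, length(iz)) }
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

# Distance (mm) from every voxel to the nearest TRUE voxel centre.
edt_mm <- function(mask, spacing) {
  d <- dim(mask)
  out <- .edt3d_cpp(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(out, dim = d)
}

# Fill NA values of `a` (restricted to `where`) from valid 6-neighbours,
# iterating until no reachable NA remains. Used to impute curvature at voxels
# where the level-set gradient vanishes or the smoothing stencil is truncated.
fill_from_neighbours <- function(a, max_iter = 1000L) {
  it <- 0L
  while (anyNA(a) && it < max_iter) {
    nas <- is.na(a)
    acc <- array(0, dim(a)); cnt <- array(0, dim(a))
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_axis(a, ax, s)
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt <- cnt + ok
    }
    upd <- nas & cnt > 0
    if (!any(upd)) break
    a[upd] <- acc[upd] / cnt[upd]
    it <- it + 1L
  }
  a
}
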