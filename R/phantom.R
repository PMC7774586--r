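# Synthetic cortical phantoms with analytic ground truth.
#
# Three ribbon geometries are supported:
#   slab   -- flat cortex between parallel planes (zero curvature oracle)
#   shell  -- spherical shell (closed-form equi-volume depth and curvature)
#   folded -- sinusoidally folded ribbon (sign-varying curvature, optionally
#             thickness varying across traverses)
#
# The phantom intensity emulates a T1-weighted contrast: a depth-dependent
# laminar profile (deep layers brighter, mimicking myelination), linear
# confound trends in curvature and thickness, a smooth multiplicative bias
# field, additive Gaussian noise, and optional regional offsets used to
# inject group effects.

#' Specify a synthetic cortical phantom
#'
#' @param shape one of "slab", "shell", "folded".
#' @param spacing_mm voxel size (mm), scalar or length 3.
#' @param thickness_mm slab cortical thickness (mm).
#' @param inner_radius_mm,outer_radius_mm shell WM-GM and GM-CSF interface
#'   radii (mm).
#' @param base_thickness_mm,fold_amplitude_mm,fold_wavelength_mm folded-ribbon
#'   thickness, fold amplitude and wavelength (mm).
#' @param thickness_mod_amplitude_mm,thickness_mod_wavelength_mm optional
#'   sinusoidal thickness modulation across traverses of the folded ribbon
#'   (mm); 0 keeps thickness constant.
#' @param intensity_profile function of depth in \[0,1\] giving the noise-free
#'   GM intensity (arbitrary units). Default decreases with depth: the deep
#'   (WM-adjacent, depth 0) layers are brightest, as in T1-w cortex.
#' @param curvature_coeff intensity units per 1/mm of curvature (imposed
#'   confound trend).
#' @param thickness_coeff intensity units per mm of thickness.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param bias_coef optional length-10 coefficients of the log bias field over
#'   the quadratic monomial basis (1, x, y, z, x^2, y^2, z^2, xy, xz, yz) in
#'   grid-normalized coordinates; the multiplicative field is exp(poly), hence
#'   always positive. NULL means no bias (field identically 1).
#' @param wm_intensity,csf_intensity noise-free tissue intensities outside GM.
#' @param grid_dim optional integer length-3 grid size; default sized to hold
#'   the ribbon plus margin.
#' @param margin_vox margin (voxels) between the ribbon and the grid border.
#' @param seed integer RNG seed for the noise realization.
#' @return An object of class `phantom_spec` (validated parameter list).
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(shape = c("slab", "shell", "folded"),
                         spacing_mm = 0.7,
                         thickness_mm = 4,
                         inner_radius_mm = 7, outer_radius_mm = 10,
                         base_thickness_mm = 3, fold_amplitude_mm = 2,
                         fold_wavelength_mm = 12,
                         thickness_mod_amplitude_mm = 0,
                         thickness_mod_wavelength_mm = 15,
                         intensity_profile = NULL,
                         curvature_coeff = 0, thickness_coeff = 0,
                         noise_sd = 0.1,
                         bias_coef = NULL,
                         wm_intensity = 2.0, csf_intensity = 0.4,
                         grid_dim = NULL, margin_vox = 8L, seed = 1L) {
  shape <- match.arg(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (shape == "slab" && thickness_mm <= 0)
    stop("slab thickness must be strictly positive")
  if (shape == "shell") {
    if (inner_radius_mm <= 0 || outer_radius_mm <= inner_radius_mm)
      stop("shell requires 0 < inner_radius_mm < outer_radius_mm")
  }
  if (shape == "folded") {
    if (base_thickness_mm <= 0) stop("base thickness must be positive")
    if (thickness_mod_amplitude_mm >= base_thickness_mm / 2)
      stop("thickness modulation would collapse the ribbon")
  }
  if (is.null(intensity_profile))
    intensity_profile <- function(d) 1.6 - 0.6 * d
  if (!is.null(bias_coef) && length(bias_coef) != 10)
    stop("bias_coef must have length 10 (quadratic monomial basis)")
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 thickness_mm = thickness_mm,
                 inner_radius_mm = inner_radius_mm,
                 outer_radius_mm = outer_radius_mm,
                 base_thickness_mm = base_thickness_mm,
                 fold_amplitude_mm = fold_amplitude_mm,
                 fold_wavelength_mm = fold_wavelength_mm,
                 thickness_mod_amplitude_mm = thickness_mod_amplitude_mm,
                 thickness_mod_wavelength_mm = thickness_mod_wavelength_mm,
                 intensity_profile = intensity_profile,
                 curvature_coeff = curvature_coeff,
                 thickness_coeff = thickness_coeff,
                 noise_sd = noise_sd, bias_coef = bias_coef,
                 wm_intensity = wm_intensity, csf_intensity = csf_intensity,
                 grid_dim = grid_dim, margin_vox = as.integer(margin_vox),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Analytic equi-volume depth of a spherical shell
#'
#' Volume fraction of the shell between the inner interface and radius `r`:
#' `(r^3 - r1^3) / (r2^3 - r1^3)`.
#'
#' @param r radius (mm), vectorized.
#' @param r1,r2 inner and outer interface radii (mm).
#' @return depth in \[0,1\].
#' @export
shell_depth_analytic <- function(r, r1, r2) {
  pmin(pmax((r^3 - r1^3) / (r2^3 - r1^3), 0), 1)
}

#' Generate a synthetic cortical phantom
#'
#' Builds the labelled tissue grid (background/CSF/GM/WM), the noisy biased
#' intensity volume, and exact ground-truth depth, curvature and thickness
#' fields for the chosen geometry. Labels are assigned by voxel-centre
#' membership, keeping the truth analytic.
#'
#' @param spec a [phantom_spec()].
#' @param offset optional 3D array (grid-sized) of additive intensity offsets
#'   applied inside GM before bias and noise; used to inject group effects.
#' @param group_offsets optional named numeric recorded in the truth (the
#'   lobe -> offset map that produced `offset`).
#' @return A list of class `phantom` with elements `intensity` (volume_grid),
#'   `labels` (volume_grid of integer codes, see [label_codes()]), and `truth`
#'   (list: `depth`, `curvature`, `thickness` volume_grids defined on GM;
#'   `gm_mask`, `brain_mask` logical arrays; `group_offsets`).
#' @examples
#' ph <- make_phantom(phantom_spec("slab", spacing_mm = 1, noise_sd = 0))
#' table(ph$labels$data)
#' @export
make_phantom <- function(spec, offset = NULL, group_offsets = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing_mm
  geom <- switch(spec$shape,
                 slab = phantom_geom_slab(spec),
                 shell = phantom_geom_shell(spec),
                 folded = phantom_geom_folded(spec))
  d <- geom$dim
  labels <- geom$labels
  gm <- labels == 2L
  if (!any(gm)) stop("phantom configuration error: empty GM ribbon")
  # background border: a closed ribbon (shell) must stay clear of the whole
  # grid boundary; open ribbons (slab, folded) span the grid laterally, so
  # only the z faces are trimmed
  border <- array(FALSE, d)
  if (spec$shape == "shell") {
    border[c(1, d[1]), , ] <- TRUE
    border[, c(1, d[2]), ] <- TRUE
  }
  border[, , c(1, d[3])] <- TRUE
  if (any(gm & border))
    stop("phantom configuration error: ribbon exceeds grid bounds")
  labels[border] <- 0L
  gm <- labels == 2L

  vg0 <- volume_grid(array(0, d), spacing = h, affine = geom$affine)
  base <- array(0, d)
  base[labels == 3L] <- spec$wm_intensity
  base[labels == 1L] <- spec$csf_intensity
  base[gm] <- spec$intensity_profile(geom$depth[gm]) +
    spec$curvature_coeff * geom$curvature[gm] +
    spec$thickness_coeff * geom$thickness[gm]
  if (!is.null(offset)) {
    stopifnot(all(dim(offset) == d))
    base[gm] <- base[gm] + offset[gm]
  }
  noise <- array(0, d)
  if (spec$noise_sd > 0) {
    nb <- labels > 0L
    noise[nb] <- local_seed(spec$seed, rnorm(sum(nb), 0, spec$noise_sd))
  }
  bias <- phantom_bias_field(vg0, spec$bias_coef)
  intensity <- bias * (base + noise)

  as_field <- function(a, on) { a[!on] <- NA_real_; a }
  mk <- function(a) volume_grid(a, spacing = h, affine = geom$affine)
  list(
    intensity = mk(intensity),
    labels = {
      lv <- mk(labels); lv$data <- array(as.integer(labels), d); lv
    },
    truth = list(
      depth = mk(as_field(geom$depth, gm)),
      curvature = mk(as_field(geom$curvature, gm)),
      thickness = mk(as_field(geom$thickness, gm)),
      gm_mask = gm,
      brain_mask = labels > 0L,
      group_offsets = group_offsets
    ),
    bias = mk(bias),
    spec = spec
  ) -> out
  class(out) <- "phantom"
  out
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$labels$data)
  cat(sprintf("<phantom> shape '%s', %d x %d x %d voxels, %d GM voxels\n",
              x$spec$shape, d[1], d[2], d[3], sum(x$truth$gm_mask)))
  invisible(x)
}

# multiplicative bias field exp(quadratic polynomial) on grid-normalized
# coordinates in [-1, 1]; NULL coefficients give a unit field
phantom_bias_field <- function(vg, coef) {
  d <- dim(vg$data)
  if (is.null(coef)) return(array(1, d))
  w <- grid_world(vg)
  nrm <- function(a) {
    rg <- range(a)
    if (diff(rg) == 0) return(a * 0)
    2 * (a - rg[1]) / diff(rg) - 1
  }
  x <- nrm(w$x); y <- nrm(w$y); z <- nrm(w$z)
  lp <- coef[1] + coef[2] * x + coef[3] * y + coef[4] * z +
    coef[5] * x^2 + coef[6] * y^2 + coef[7] * z^2 +
    coef[8] * x * y + coef[9] * x * z + coef[10] * y * z
  exp(lp)
}

# ---- geometry builders ----------------------------------------------------

# Slab: WM below z = 0, GM for 0 < z < T, CSF above. The z grid is laid out
# so that voxel centres sit at (k + 1/2) h, putting both interfaces exactly
# on voxel faces.
phantom_geom_slab <- function(spec) {
  h <- spec$spacing_mm
  T <- spec$thickness_mm
  m <- spec$margin_vox
  n_gm <- ceiling(T / h[3])
  nz <- n_gm + 2L * (m + 2L)
  if (is.null(spec$grid_dim)) {
    nx <- 2L * m + 20L; ny <- 2L * m + 20L
  } else {
    nx <- spec$grid_dim[1]; ny <- spec$grid_dim[2]; nz <- spec$grid_dim[3]
  }
  d <- c(nx, ny, nz)
  A <- diag(c(h, 1))
  # voxel k (0-based) centre at (k + 0.5 - (m + 2)) * h along z
  A[3, 4] <- (0.5 - (m + 2L)) * h[3]
  A[1, 4] <- -(nx - 1) / 2 * h[1]
  A[2, 4] <- -(ny - 1) / 2 * h[2]
  vg <- volume_grid(array(0, d), spacing = h, affine = A)
  w <- grid_world(vg)
  z <- w$z
  labels <- array(1L, d)           # CSF above
  labels[z < 0] <- 3L              # WM below
  labels[z > 0 & z < T] <- 2L      # GM ribbon
  depth <- z / T
  list(dim = d, affine = A, labels = labels, depth = depth,
       curvature = array(0, d), thickness = array(T, d))
}

# Shell: WM core r < r1, GM ribbon r1 < r < r2, CSF outside. Depth truth is
# the closed-form volume fraction; curvature truth 1/r per voxel (sphere).
phantom_geom_shell <- function(spec) {
  h <- spec$spacing_mm
  r1 <- spec$inner_radius_mm; r2 <- spec$outer_radius_mm
  m <- spec$margin_vox
  if (is.null(spec$grid_dim)) {
    n <- 2L * (ceiling(r2 / min(h)) + m) + 1L
    d <- rep(n, 3)
  } else d <- spec$grid_dim
  A <- centered_affine(d, h)
  vg <- volume_grid(array(0, d), spacing = h, affine = A)
  w <- grid_world(vg)
  r <- sqrt(w$x^2 + w$y^2 + w$z^2)
  if (r2 + 2 * max(h) > min((d - 1) / 2 * h))
    stop("phantom configuration error: shell exceeds grid bounds")
  labels <- array(1L, dim = d)
  labels[r < r1] <- 3L
  labels[r >= r1 & r <= r2] <- 2L
  depth <- shell_depth_analytic(r, r1, r2)
  curv <- 1 / pmax(r, min(h) / 2)
  list(dim = d, affine = A, labels = labels, depth = depth,
       curvature = curv, thickness = array(r2 - r1, dim = d))
}

# Folded ribbon: mid-surface z = a sin(2 pi x / lambda), extruded along y,
# with surfaces at normal offsets +/- T(y)/2. Signed distance to the
# mid-surface is computed against a densely sampled curve, so labels and
# depth remain exact up to the sampling step (0.02 mm).
phantom_geom_folded <- function(spec) {
  h <- spec$spacing_mm
  T0 <- spec$base_thickness_mm
  a <- spec$fold_amplitude_mm
  lam <- spec$fold_wavelength_mm
  at <- spec$thickness_mod_amplitude_mm
  lamt <- spec$thickness_mod_wavelength_mm
  m <- spec$margin_vox
  if (is.null(spec$grid_dim)) {
    ex <- 2 * lam
    ey <- if (at > 0) 1.5 * lamt else 14
    ez <- 2 * (a + T0 / 2 + at) + 4
    d <- c(ceiling(ex / h[1]) + 2L * m, ceiling(ey / h[2]) + 2L * m,
           ceiling(ez / h[3]) + 2L * m)
  } else d <- spec$grid_dim
  A <- centered_affine(d, h)
  vg <- volume_grid(array(0, d), spacing = h, affine = A)
  w <- grid_world(vg)

  f  <- function(x) a * sin(2 * pi * x / lam)
  fp <- function(x) a * (2 * pi / lam) * cos(2 * pi * x / lam)
  fpp <- function(x) -a * (2 * pi / lam)^2 * sin(2 * pi * x / lam)

  # signed distance of each (x, z) to the curve (x', f(x')); y separates out
  xs <- unique(as.vector(w$x[, 1, 1]))
  zs <- unique(as.vector(w$z[1, 1, ]))
  pad <- 1.5 * lam
  xc <- seq(min(xs) - pad, max(xs) + pad, by = 0.02)
  zc <- f(xc)
  nearest <- function(x0, z0) {
    dd <- (xc - x0)^2 + (zc - z0)^2
    i <- which.min(dd)
    c(sqrt(dd[i]), xc[i])
  }
  nx <- length(xs); nz <- length(zs)
  dmat <- matrix(0, nx, nz); xstar <- matrix(0, nx, nz)
  for (i in seq_len(nx)) for (k in seq_len(nz)) {
    nn <- nearest(xs[i], zs[k])
    s <- if (zs[k] >= f(xs[i])) 1 else -1
    dmat[i, k] <- s * nn[1]
    xstar[i, k] <- nn[2]
  }
  dim3 <- function(mk) {
    # expand (x, z) matrix to the full grid along y
    array(mk[cbind(rep(rep(seq_len(nx), times = 1), times = d[2] * nz),
                   rep(seq_len(nz), each = nx * d[2]))], d)
  }
  dsgn <- dim3(dmat)
  xst <- dim3(xstar)
  Ty <- T0 + if (at > 0) at * sin(2 * pi * w$y / lamt) else 0
  if (length(Ty) == 1) Ty <- array(T0, d)

  labels <- array(1L, d)
  labels[dsgn < -Ty / 2] <- 3L
  labels[abs(dsgn) <= Ty / 2] <- 2L
  depth <- pmin(pmax((dsgn + Ty / 2) / Ty, 0), 1)
  k0 <- -fpp(xst) / (1 + fp(xst)^2)^1.5
  kd <- k0 / pmax(abs(1 + dsgn * k0), 0.2) * sign(1 + dsgn * k0)
  curv <- kd / 2   # cylindrical surface: one principal curvature is zero
  list(dim = d, affine = A, labels = labels, depth = depth,
       curvature = curv, thickness = Ty)
}
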