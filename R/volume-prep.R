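# Volume preparation: trilinear resampling on the original field of view,
# polynomial bias-field normalization of log-intensity, morphological mask
# dilation, and mask application.

#' Resample a volume to a new voxel spacing
#'
#' Trilinear interpolation on the world-space grid implied by the original
#' field of view (extent = dim * spacing, cell-centred voxels). The new grid
#' has `ceiling(extent / target)` samples per axis; positions outside the
#' source extent take the nearest-edge value.
#'
#' @param vol a `volume_grid`.
#' @param target_spacing_mm new voxel size, scalar or per axis (mm, > 0).
#' @param method `"trilinear"` for scalar volumes (default), `"nearest"`
#'   for label volumes.
#' @return Resampled `volume_grid` with updated affine.
#' @examples
#' vg <- volume_grid(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = 1)
#' dim(resample_volume(vg, 0.5)$data)
#' @export
resample_volume <- function(vol, target_spacing_mm,
                            method = c("trilinear", "nearest")) {
  stopifnot(inherits(vol, "volume_grid"))
  method <- match.arg(method)
  tsp <- as.numeric(target_spacing_mm)
  if (length(tsp) == 1) tsp <- rep(tsp, 3)
  if (any(!is.finite(tsp)) || any(tsp <= 0))
    stop("target spacing must be strictly positive")
  d <- dim(vol$data)
  sp <- vol$spacing
  extent <- d * sp
  dn <- as.integer(ceiling(extent / tsp))
  # fractional source index (1-based) of new voxel centre i (1-based):
  # x = (i - 0.5) * tsp  ->  idx = x / sp + 0.5
  src <- lapply(1:3, function(ax)
    ((seq_len(dn[ax]) - 0.5) * tsp[ax]) / sp[ax] + 0.5)
  ix <- rep(src[[1]], times = dn[2] * dn[3])
  iy <- rep(rep(src[[2]], each = dn[1]), times = dn[3])
  iz <- rep(src[[3]], each = dn[1] * dn[2])
  vals <- if (method == "nearest") {
    cl <- function(i, n) pmin(pmax(round(i), 1), n)
    vol$data[cbind(cl(ix, d[1]), cl(iy, d[2]), cl(iz, d[3]))]
  } else {
    trilinear(vol$data, ix, iy, iz)
  }
  # new affine: i_old0 = (i_new0 + 0.5) * tsp / sp - 0.5
  S <- diag(4)
  diag(S)[1:3] <- tsp / sp
  S[1:3, 4] <- 0.5 * tsp / sp - 0.5
  volume_grid(array(vals, dn), spacing = tsp, affine = vol$affine %*% S,
              space = vol$space)
}

# Trivariate monomial basis up to total degree `order` on coordinates scaled
# to [-1, 1] within the mask extent.
poly_basis <- function(x, y, z, order) {
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1L]] <- x^i * y^j * z^k
  do.call(cbind, cols)
}

#' Normalize intensity inhomogeneity
#'
#' Estimates a smooth multiplicative bias field as `exp(polynomial)` fitted
#' by least squares to the log-intensity within a reference region assumed
#' homogeneous up to the bias (typically the white-matter mask, as in
#' WM-based normalization), and divides the field out of the whole volume.
#' The polynomial (default total degree 3) is parameterized in world
#' coordinates scaled to the volume extent; the field is normalized to unit
#' log-mean over the reference region and the output is rescaled so the
#' mean inside the region matches the input.
#'
#' @param vol a `volume_grid` with strictly positive intensities inside the
#'   mask.
#' @param mask logical array: the homogeneous reference region over which
#'   the field is estimated.
#' @param order polynomial total degree of the log-bias model.
#' @return Normalized `volume_grid`; the fitted field is attached as
#'   attribute `"bias_field"` (array over the full grid).
#' @export
normalize_intensity <- function(vol, mask, order = 3) {
  stopifnot(inherits(vol, "volume_grid"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  v <- vol$data[mask]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("non-positive or non-finite intensities inside mask; log-bias model undefined")
  n_coef <- choose(order + 3, 3)
  if (sum(mask) <= n_coef)
    stop("mask too small (", sum(mask), " voxels) for a degree-", order,
         " bias model (", n_coef, " coefficients)")
  w <- grid_world(vol)
  nrm <- function(a) {
    rg <- range(a)
    if (diff(rg) == 0) return(a * 0)
    2 * (a - rg[1]) / diff(rg) - 1
  }
  x <- nrm(w$x); y <- nrm(w$y); z <- nrm(w$z)
  X <- poly_basis(x[mask], y[mask], z[mask], order)
  fit <- lm.fit(X, log(v))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  logb_in <- drop(X %*% co)
  shift <- mean(logb_in)               # unit log-mean over the reference
  Xall <- poly_basis(as.vector(x), as.vector(y), as.vector(z), order)
  bias <- array(exp(drop(Xall %*% co) - shift), dim(vol$data))
  out <- vol
  out$data <- vol$data / bias
  sc <- mean(v) / mean(out$data[mask])
  out$data <- out$data * sc
  attr(out, "bias_field") <- bias
  out
}

#' Dilate a binary mask
#'
#' Morphological dilation with the face-connected (6-neighbour) structuring
#' element, applied `iterations` times. Monotone: the output contains the
#' input; composition adds up (`a` then `b` equals `a + b`).
#'
#' @param mask logical 3D array.
#' @param iterations non-negative integer.
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  if (iterations < 0) stop("iterations must be >= 0")
  m <- as.array(mask)
  storage.mode(m) <- "logical"
  it <- as.integer(iterations)
  while (it > 0L) {
    out <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      sh <- shift_axis(m, ax, s)
      # undo the clamp-to-edge replication so dilation does not wrap the border
      d <- dim(m)
      idx <- lapply(d, seq_len)
      bidx <- idx
      bidx[[ax]] <- if (s == 1L) 1L else d[ax]
      sh[bidx[[1]], bidx[[2]], bidx[[3]]] <- FALSE
      out <- out | sh
    }
    m <- out
    it <- it - 1L
  }
  m
}

#' Apply a binary mask to a volume
#'
#' Voxels outside the mask are set to 0; inside they are unchanged.
#'
#' @param vol a `volume_grid`.
#' @param mask logical array of the same shape.
#' @return Masked `volume_grid`.
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!all(dim(mask) == dim(vol$data)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume ", paste(dim(vol$data), collapse = "x"))
  out <- vol
  out$data[!mask] <- 0
  out
}
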