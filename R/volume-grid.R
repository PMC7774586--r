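#' 3D scalar volume with spacing and affine
#'
#' The basic spatial container of the package: a 3D array of voxel values plus
#' the voxel size per axis (mm) and a 4x4 voxel-to-world affine mapping
#' 0-based voxel indices to world coordinates (RAS+ by convention). All
#' millimetre quantities in the package are derived through the affine, never
#' from index counts.
#'
#' @param data 3D numeric (or integer/logical) array.
#' @param spacing numeric length-3, voxel size per axis in mm (> 0).
#' @param affine 4x4 voxel-to-world matrix; default diagonal spacing with the
#'   grid centre at the world origin.
#' @param space free-text space label (e.g. "subject", "reference").
#' @return An object of class `volume_grid`: a list with elements `data`,
#'   `spacing`, `affine`, `space`.
#' @examples
#' vg <- volume_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(vg$data)
#' @export
volume_grid <- function(data, spacing, affine = NULL, space = "subject") {
  if (length(dim(data)) != 3)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (is.null(affine)) affine <- centered_affine(dim(data), spacing)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 space = space),
            class = "volume_grid")
}

#' Affine placing the grid centre at the world origin
#'
#' @param dim integer length-3 grid dimensions.
#' @param spacing voxel size per axis (mm).
#' @return 4x4 voxel-to-world matrix (0-based voxel indices).
#' @export
centered_affine <- function(dim, spacing) {
  A <- diag(c(spacing, 1))
  A[1:3, 4] <- -(dim - 1) / 2 * spacing
  A
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, space '%s'\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x "),
              x$space))
  v <- x$data[is.finite(x$data)]
  if (length(v))
    cat(sprintf("  finite range: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

# World coordinates (n x 3, mm) of 1-based voxel index rows `idx` (n x 3).
voxel_world <- function(vg, idx) {
  idx0 <- cbind(idx - 1, 1)
  t(vg$affine %*% t(idx0))[, 1:3, drop = FALSE]
}

# World coordinates of every voxel as three arrays (list x, y, z).
grid_world <- function(vg) {
  d <- dim(vg$data)
  i <- (seq_len(d[1]) - 1); j <- (seq_len(d[2]) - 1); k <- (seq_len(d[3]) - 1)
  A <- vg$affine
  x <- A[1, 1] * i; y <- A[2, 2] * j; z <- A[3, 3] * k
  # general affine support (rotation/shear) falls back to full expansion
  if (any(A[1:3, 1:3][lower.tri(matrix(0, 3, 3)) | upper.tri(matrix(0, 3, 3))] != 0)) {
    ijk <- as.matrix(expand.grid(i = i, j = j, k = k))
    w <- t(A %*% t(cbind(ijk, 1)))
    return(list(x = array(w[, 1], d), y = array(w[, 2], d), z = array(w[, 3], d)))
  }
  list(x = array(rep(x + A[1, 4], times = d[2] * d[3]), d),
       y = array(rep(rep(y + A[2, 4], each = d[1]), times = d[3]), d),
       z = array(rep(z + A[3, 4], each = d[1] * d[2]), d))
}

#' Tissue label codes used by the package
#'
#' Segmentation volumes code voxels as background 0, CSF 1, grey matter 2,
#' white matter 3.
#' @return Named integer vector of label codes.
#' @export
label_codes <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1/2 file (.nii or .nii.gz).
#' @param space space label to attach.
#' @return A [volume_grid].
#' @export
read_volume <- function(path, space = "subject") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI at ", path, ": ",
                                           conditionMessage(e)))
  if (length(dim(img)) != 3)
    stop("expected a 3D volume at ", path, ", got ",
         length(dim(img)), " dimensions")
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(sp <= 0)) sp <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim(img)), spacing = sp,
              affine = aff, space = space)
}

#' Write a volume as NIfTI
#'
#' Spacing and affine round-trip exactly through [read_volume()].
#'
#' @param vol a [volume_grid].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  # store the affine as the sform: the quaternion (qform) representation
  # cannot carry anisotropic scaling faithfully through RNifti
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
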