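canonical_xform <- function(img) {
  orient <- RNifti::orientation(img)
  if (!identical(orient, "RAS")) RNifti::orientation(img) <- "RAS"
  img
}

xform_geometry <- function(img, path) {
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0))
    stop(sprintf("'%s': degenerate affine (zero spacing)", path), call. = FALSE)
  dircos <- sweep(rot, 2, spacing, "/")
  if (max(abs(abs(dircos) - diag(3))) > 1e-3)
    stop(sprintf("'%s': oblique affine (direction cosines deviate from the axes by more than 1e-3); reslice upstream", path),
         call. = FALSE)
  list(spacing = spacing, origin = xf[1:3, 4])
}

read_nifti_checked <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  tryCatch(RNifti::readNifti(path),
           error = function(e) stop(sprintf("cannot read '%s' as NIfTI: %s",
                                            path, conditionMessage(e)), call. = FALSE))
}

#' Read a scalar volume from NIfTI
#'
#' Reads a 3D NIfTI file, reorients it to the canonical (RAS) axis order, and
#' returns a [scalar_volume()] whose spacing and origin reflect the file's
#' affine. Oblique affines (direction cosines off-axis by more than 1e-3) are
#' rejected rather than silently resliced.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  img <- canonical_xform(read_nifti_checked(path))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s': expected a 3D volume, got %d dimensions", path, length(d)),
         call. = FALSE)
  geo <- xform_geometry(img, path)
  scalar_volume(array(as.numeric(img), d), spacing = geo$spacing, origin = geo$origin)
}

make_nifti <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(4)
  aff[1, 1] <- grid$spacing[1]
  aff[2, 2] <- grid$spacing[2]
  aff[3, 3] <- grid$spacing[3]
  aff[1:3, 4] <- grid$origin
  aff <- structure(aff, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  img
}

check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("cannot write '%s': directory does not exist", path), call. = FALSE)
  if (file.access(dir, 2L) != 0L)
    stop(sprintf("cannot write '%s': directory not writable", path), call. = FALSE)
  invisible(TRUE)
}

#' Write a scalar volume to NIfTI
#'
#' Values are stored as 64-bit floats so a write/read round trip is exact.
#'
#' @param volume a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  check_writable(path)
  RNifti::writeNifti(make_nifti(volume$values, volume$grid), path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Nonzero voxels are foreground.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$values != 0, grid = vol$grid)
}

#' Write a binary mask to NIfTI (0/1 integers)
#'
#' @param mask a [binary_mask()].
#' @inheritParams write_volume
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  check_writable(path)
  arr <- array(as.integer(mask$values), dim(mask$values))
  RNifti::writeNifti(make_nifti(arr, mask$grid), path, datatype = "uint8")
  invisible(path)
}

#' Read a displacement field from a 3-component NIfTI
#'
#' Expects a 4D file whose fourth dimension holds the (x, y, z) displacement
#' components in mm.
#'
#' @inheritParams read_volume
#' @return A [displacement_field()].
#' @export
read_dvf <- function(path) {
  img <- read_nifti_checked(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop(sprintf("'%s': expected a 4D vector field with 3 components", path),
         call. = FALSE)
  geo <- xform_geometry(img, path)
  displacement_field(array(as.numeric(img), d), spacing = geo$spacing,
                     origin = geo$origin)
}

#' Write a displacement field as a 3-component NIfTI
#'
#' @param dvf a [displacement_field()] or [velocity_field()].
#' @inheritParams write_volume
#' @return `path`, invisibly.
#' @export
write_dvf <- function(dvf, path) {
  stopifnot(inherits(dvf, "displacement_field") || inherits(dvf, "velocity_field"))
  check_writable(path)
  RNifti::writeNifti(make_nifti(dvf$vectors, dvf$grid), path, datatype = "double")
  invisible(path)
}
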