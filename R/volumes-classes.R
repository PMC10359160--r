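#' @useDynLib dvfsynth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils write.csv modifyList
NULL

#' Voxel grid with physical geometry
#'
#' Describes the sampling lattice shared by scalar volumes, masks, and
#' deformation fields: the number of voxels per axis, the voxel spacing in mm,
#' and the physical position (mm) of voxel (1,1,1). Axes are ordered (x, y, z)
#' with z the superior-inferior direction; physical position of voxel index
#' `i` (1-based) is `origin + (i - 1) * spacing`.
#'
#' @param shape integer triple, voxels per axis; every component must be >= 2
#'   so that finite differences are defined.
#' @param spacing positive real triple, mm per voxel.
#' @param origin real triple, mm.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing = c(2.5, 2.5, 2.5), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be positive", call. = FALSE)
  if (any(is.na(shape)) || any(shape < 2L))
    stop("all shape components must be >= 2", call. = FALSE)
  if (any(!is.finite(origin)))
    stop("origin must be finite", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grids_equal(a, b))
    stop(sprintf("%s must share the same grid (shape, spacing, origin)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Physical coordinate arrays of a grid
#'
#' Returns the physical (mm) coordinate of every voxel along each axis as three
#' arrays of the grid's shape.
#'
#' @param grid a [volume_grid()].
#' @return A list with arrays `x`, `y`, `z`.
#' @export
grid_coordinates <- function(grid) {
  s <- grid$shape
  ax <- grid$origin[1] + (seq_len(s[1]) - 1) * grid$spacing[1]
  ay <- grid$origin[2] + (seq_len(s[2]) - 1) * grid$spacing[2]
  az <- grid$origin[3] + (seq_len(s[3]) - 1) * grid$spacing[3]
  list(x = array(ax, s),
       y = array(rep(ay, each = s[1]), s),
       z = array(rep(az, each = s[1] * s[2]), s))
}

#' Scalar CT-like volume
#'
#' A 3D intensity grid in Hounsfield-style units together with its physical
#' geometry. This is the container for diagnostic (dCT), planning (pCT), and
#' synthesized (sCT) scans.
#'
#' @param values 3D numeric array, finite, with dim equal to `grid$shape`.
#' @param grid a [volume_grid()]; if missing, built from `spacing`/`origin`.
#' @param spacing,origin convenience alternatives to `grid`.
#' @return An object of class `scalar_volume` with fields `grid` and `values`.
#' @export
scalar_volume <- function(values, grid = NULL, spacing = c(2.5, 2.5, 2.5),
                          origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array", call. = FALSE)
  if (is.null(grid)) grid <- volume_grid(dim(values), spacing, origin)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values shape must equal grid shape", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all intensity values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, range [%.1f, %.1f]\n",
              paste(x$grid$shape, collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask
#'
#' Boolean volume marking a delineated structure (body, lungs, GTV) on a grid.
#'
#' @param values 3D logical (or coercible) array.
#' @inheritParams scalar_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid = NULL, spacing = c(2.5, 2.5, 2.5),
                        origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array", call. = FALSE)
  if (is.null(grid)) grid <- volume_grid(dim(values), spacing, origin)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values shape must equal grid shape", call. = FALSE)
  if (anyNA(values)) stop("mask values must not contain NA", call. = FALSE)
  mode(values) <- "logical"
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(x$grid$shape, collapse = " x "), sum(x$values)))
  invisible(x)
}

new_vector_field <- function(vectors, grid, spacing, origin, class) {
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("vectors must be a 4D array with 3 components in the last dimension",
         call. = FALSE)
  if (is.null(grid)) grid <- volume_grid(dim(vectors)[1:3], spacing, origin)
  if (!identical(dim(vectors)[1:3], as.integer(grid$shape)))
    stop("vectors spatial shape must equal grid shape", call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("all vector components must be finite", call. = FALSE)
  storage.mode(vectors) <- "double"
  structure(list(grid = grid, vectors = vectors), class = class)
}

#' Dense displacement field (DVF)
#'
#' A per-voxel 3-component displacement in mm on physical axes, using the
#' pull-back (resampling) convention: the warped image at position `p` samples
#' the source image at `p + u(p)`.
#'
#' @param vectors 4D numeric array `(x, y, z, component)`, mm.
#' @inheritParams scalar_volume
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid = NULL, spacing = c(2.5, 2.5, 2.5),
                               origin = c(0, 0, 0)) {
  new_vector_field(vectors, grid, spacing, origin, "displacement_field")
}

#' Stationary velocity field
#'
#' The raw 3-component field (mm) produced by the generator, interpreted as a
#' stationary velocity whose exponential (via [integrate_velocity()]) is a
#' diffeomorphic displacement field.
#'
#' @inheritParams displacement_field
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(vectors, grid = NULL, spacing = c(2.5, 2.5, 2.5),
                           origin = c(0, 0, 0)) {
  new_vector_field(vectors, grid, spacing, origin, "velocity_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %s voxels, max |u| = %.2f mm\n",
              paste(x$grid$shape, collapse = " x "), max(abs(x$vectors))))
  invisible(x)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s voxels, max |v| = %.2f mm\n",
              paste(x$grid$shape, collapse = " x "), max(abs(x$vectors))))
  invisible(x)
}

#' Zero displacement field on a grid
#' @param grid a [volume_grid()].
#' @return A [displacement_field()] of all zeros.
#' @export
zero_displacement <- function(grid) {
  displacement_field(array(0, c(grid$shape, 3L)), grid = grid)
}
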