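# 0-based voxel index arrays of a grid (query helpers for the C++ sampler)
base_voxel_coords <- function(shape) {
  list(x = array(seq_len(shape[1]) - 1, shape),
       y = array(rep(seq_len(shape[2]) - 1, each = shape[1]), shape),
       z = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape))
}

check_interp <- function(interpolation) {
  match.arg(interpolation, c("linear", "nearest"))
}

#' Resample a volume to a new voxel spacing
#'
#' Resamples onto a grid with the requested spacing, preserving the physical
#' extent of the volume within one voxel (the first sample stays at the
#' original origin; the number of samples along each axis is chosen so the
#' point-to-point extent is preserved as closely as possible).
#'
#' @param volume a [scalar_volume()].
#' @param target_spacing positive real triple (mm), e.g. `c(2.5, 2.5, 2.5)`.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A [scalar_volume()] on the new grid.
#' @export
resample <- function(volume, target_spacing, interpolation = c("linear", "nearest")) {
  stopifnot(inherits(volume, "scalar_volume"))
  interpolation <- check_interp(interpolation)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target_spacing must be a positive real triple", call. = FALSE)
  g <- volume$grid
  extent <- (g$shape - 1) * g$spacing
  new_shape <- pmax(2L, as.integer(round(extent / target_spacing)) + 1L)
  new_grid <- volume_grid(new_shape, target_spacing, g$origin)
  q <- base_voxel_coords(new_shape)
  # physical position of the new sample, expressed in source voxel coordinates
  vals <- cpp_sample3d(volume$values, g$shape,
                       q$x * (target_spacing[1] / g$spacing[1]),
                       q$y * (target_spacing[2] / g$spacing[2]),
                       q$z * (target_spacing[3] / g$spacing[3]),
                       interpolation == "linear")
  scalar_volume(array(vals, new_shape), grid = new_grid)
}

#' Warp a volume with a displacement field
#'
#' Pull-back warping: the output value at voxel position `p` (mm) is the input
#' sampled at `p + u(p)`. Samples outside the domain replicate the nearest
#' edge value.
#'
#' @param volume a [scalar_volume()].
#' @param dvf a [displacement_field()] on the same grid, mm.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @param boundary boundary rule; only `"replicate"` is supported.
#' @return The warped [scalar_volume()].
#' @export
warp <- function(volume, dvf, interpolation = c("linear", "nearest"),
                 boundary = "replicate") {
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(dvf, "displacement_field"))
  interpolation <- check_interp(interpolation)
  boundary <- match.arg(boundary, "replicate")
  stop_if_grid_mismatch(volume$grid, dvf$grid, "volume and dvf")
  g <- volume$grid
  q <- base_voxel_coords(g$shape)
  vals <- cpp_sample3d(volume$values, g$shape,
                       q$x + dvf$vectors[, , , 1] / g$spacing[1],
                       q$y + dvf$vectors[, , , 2] / g$spacing[2],
                       q$z + dvf$vectors[, , , 3] / g$spacing[3],
                       interpolation == "linear")
  scalar_volume(array(vals, g$shape), grid = g)
}

#' Warp a binary mask with a displacement field
#'
#' The 0/1 indicator is warped with trilinear interpolation and thresholded at
#' 0.5, which tracks the deformed boundary with sub-voxel accuracy (plain
#' nearest-neighbor warping would re-quantize it to whole voxels).
#'
#' @param mask a [binary_mask()].
#' @inheritParams warp
#' @return The warped [binary_mask()].
#' @export
warp_mask <- function(mask, dvf) {
  stopifnot(inherits(mask, "binary_mask"), inherits(dvf, "displacement_field"))
  stop_if_grid_mismatch(mask$grid, dvf$grid, "mask and dvf")
  vol <- scalar_volume(array(as.numeric(mask$values), mask$grid$shape),
                       grid = mask$grid)
  out <- warp(vol, dvf, interpolation = "linear")
  binary_mask(out$values > 0.5, grid = mask$grid)
}

#' Local interpolation hull of a warp
#'
#' For each output voxel of `warp(volume, dvf, "linear")`, returns the minimum
#' and maximum of the 8 source voxels entering the trilinear stencil. Since
#' trilinear interpolation is a convex combination, the warped value always
#' lies inside this hull; the diagnostic certifies that synthesis introduces
#' no Hounsfield values beyond local input extrema.
#'
#' @inheritParams warp
#' @return A list with [scalar_volume()]s `lo` and `hi`.
#' @export
interpolation_hull <- function(volume, dvf) {
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(dvf, "displacement_field"))
  stop_if_grid_mismatch(volume$grid, dvf$grid, "volume and dvf")
  g <- volume$grid
  q <- base_voxel_coords(g$shape)
  h <- cpp_sample3d_hull(volume$values, g$shape,
                         q$x + dvf$vectors[, , , 1] / g$spacing[1],
                         q$y + dvf$vectors[, , , 2] / g$spacing[2],
                         q$z + dvf$vectors[, , , 3] / g$spacing[3])
  list(lo = scalar_volume(array(h$lo, g$shape), grid = g),
       hi = scalar_volume(array(h$hi, g$shape), grid = g))
}

nonempty_slice_range <- function(mask) {
  nz <- which(apply(mask$values, 3, any))
  if (length(nz) == 0L) return(integer(0))
  range(nz)
}

#' Overlapping z-slice interval of two masks
#'
#' Scans with different superior-inferior coverage are compared only on
#' overlapping axial slices. Each mask contributes the inclusive interval from
#' its first to its last nonempty slice; the returned interval is the
#' intersection, expressed in the z indexing of `maskA` (1-based). The masks
#' must share the x,y grid and z spacing; their z origins may differ by an
#' integer number of slices.
#'
#' @param maskA,maskB [binary_mask()]s.
#' @return `c(lo, hi)` (1-based, inclusive), or `integer(0)` when empty.
#' @export
overlapping_z_range <- function(maskA, maskB) {
  stopifnot(inherits(maskA, "binary_mask"), inherits(maskB, "binary_mask"))
  ga <- maskA$grid; gb <- maskB$grid
  if (!identical(ga$shape[1:2], gb$shape[1:2]) ||
      any(abs(ga$spacing - gb$spacing) > 1e-6) ||
      any(abs(ga$origin[1:2] - gb$origin[1:2]) > 1e-6))
    stop("masks must share the x,y grid and voxel spacing", call. = FALSE)
  zoff <- (gb$origin[3] - ga$origin[3]) / ga$spacing[3]
  if (abs(zoff - round(zoff)) > 1e-6)
    stop("mask z grids are not slice-aligned", call. = FALSE)
  zoff <- as.integer(round(zoff))
  ra <- nonempty_slice_range(maskA)
  rb <- nonempty_slice_range(maskB)
  if (length(ra) == 0L || length(rb) == 0L) return(integer(0))
  lo <- max(ra[1], rb[1] + zoff)
  hi <- min(ra[2], rb[2] + zoff)
  if (lo > hi) return(integer(0))
  c(lo, hi)
}
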