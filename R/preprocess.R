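ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

morph_close <- function(vals, radius = 2) {
  off <- ball_offsets(radius)
  dims <- dim(vals)
  dil <- cpp_dilate(as.logical(vals), dims, off)
  # erosion as complement-dilate-complement (voxels beyond the array border
  # count as background, so the body edge at the volume boundary is kept thin)
  ero <- !cpp_dilate(!dil, dims, off)
  array(ero, dims)
}

#' Segment the patient body
#'
#' Thresholds the volume, keeps the largest 3D 6-connected component (which
#' separates the patient from the treatment couch), applies a morphological
#' closing (ball radius 2 voxels) and fills holes per axial slice, so internal
#' air (lungs, bowel gas) belongs to the body.
#'
#' @param volume a [scalar_volume()].
#' @param threshold_hu foreground threshold in HU (default -300).
#' @return A [binary_mask()] of the body.
#' @export
segment_body <- function(volume, threshold_hu = -300) {
  stopifnot(inherits(volume, "scalar_volume"))
  fg <- volume$values > threshold_hu
  if (!any(fg))
    stop("no voxels above the threshold: cannot segment a body", call. = FALSE)
  dims <- volume$grid$shape
  largest <- cpp_largest_component(as.logical(fg), dims)
  closed <- morph_close(array(largest, dims), radius = 2)
  filled <- cpp_fill_slices(as.logical(closed), dims)
  binary_mask(array(filled, dims), grid = volume$grid)
}

#' Remove the couch (and any other exterior structure)
#'
#' Sets every voxel outside the body mask to air (-1000 HU), leaving body
#' voxels untouched.
#'
#' @param volume a [scalar_volume()].
#' @param body a [binary_mask()] on the same grid.
#' @return A [scalar_volume()].
#' @export
remove_couch <- function(volume, body) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(body, "binary_mask"))
  stop_if_grid_mismatch(volume$grid, body$grid, "volume and body mask")
  vals <- volume$values
  vals[!body$values] <- -1000
  scalar_volume(vals, grid = volume$grid)
}

#' Couch geometry descriptor
#'
#' Describes a treatment/diagnostic couch as a band posterior to the patient
#' (posterior = +y). A `"flat"` couch is a slab below `top_y`; a `"curved"`
#' couch is an arc band of the given curvature radius whose apex touches
#' `top_y`. Widths and positions in mm.
#'
#' @param style `"flat"` or `"curved"`.
#' @param top_y y coordinate (mm) of the couch top surface.
#' @param thickness couch thickness (mm).
#' @param width couch width along x (mm).
#' @param center_x x coordinate (mm) of the couch center.
#' @param curvature_radius arc radius (mm) for the curved style.
#' @param hu couch intensity (HU).
#' @return An object of class `couch_model`.
#' @export
couch_model <- function(style = c("flat", "curved"), top_y, thickness = 12,
                        width, center_x, curvature_radius = 400, hu = 200) {
  style <- match.arg(style)
  stopifnot(is.finite(top_y), thickness > 0, width > 0, curvature_radius > 0)
  structure(list(style = style, top_y = top_y, thickness = thickness,
                 width = width, center_x = center_x,
                 curvature_radius = curvature_radius, hu = hu),
            class = "couch_model")
}

# top surface of the couch as a function of x: flat, or a concave trough whose
# lateral edges rise anteriorly (toward -y) following an arc of the given radius
couch_top_y <- function(model, x) {
  if (model$style == "flat") {
    rep(model$top_y, length(x))
  } else {
    r <- model$curvature_radius
    dx2 <- pmin((x - model$center_x)^2, r^2)
    model$top_y - (r - sqrt(r^2 - dx2))
  }
}

# signed depth below the couch top surface; in [0, thickness] means inside
couch_depth <- function(model, x, y) {
  y - couch_top_y(model, x)
}

#' Analytic couch mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param model a [couch_model()].
#' @return A [binary_mask()].
#' @export
couch_mask <- function(grid, model) {
  stopifnot(inherits(model, "couch_model"))
  co <- grid_coordinates(grid)
  depth <- couch_depth(model, co$x, co$y)
  inside <- depth >= 0 & depth <= model$thickness &
    abs(co$x - model$center_x) <= model$width / 2
  binary_mask(inside, grid = grid)
}

#' Digitally add a couch to a volume
#'
#' Sets couch voxels to the model's HU. Errors if the couch region overlaps
#' tissue (any voxel above -300 HU), since the couch must sit in air.
#'
#' @param volume a [scalar_volume()].
#' @param model a [couch_model()].
#' @return A [scalar_volume()].
#' @export
add_couch <- function(volume, model) {
  stopifnot(inherits(volume, "scalar_volume"))
  cm <- couch_mask(volume$grid, model)
  if (!any(cm$values)) return(volume)
  if (any(volume$values[cm$values] > -300))
    stop("couch geometry overlaps non-air voxels", call. = FALSE)
  vals <- volume$values
  vals[cm$values] <- model$hu
  scalar_volume(vals, grid = volume$grid)
}

#' Normalize intensities to [-1, 1]
#'
#' Affine map of the window `[min, max]` onto `[-1, 1]`, clipped outside. The
#' default window `[-1000, 1000]` HU spans lung to bone without saturating
#' soft tissue.
#'
#' @param volume a [scalar_volume()].
#' @param window length-2 numeric, `min < max`.
#' @return A [scalar_volume()] with values in `[-1, 1]`.
#' @export
normalize_intensity <- function(volume, window = c(-1000, 1000)) {
  stopifnot(inherits(volume, "scalar_volume"))
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be a finite pair with min < max", call. = FALSE)
  scalar_volume(normalize_values(volume$values, window), grid = volume$grid)
}

normalize_values <- function(x, window) {
  x <- pmin(pmax(x, window[1]), window[2])
  array(2 * (x - window[1]) / (window[2] - window[1]) - 1, dim(x))
}

#' Invert [normalize_intensity()]
#'
#' Maps `[-1, 1]` back to the window; composed with normalization it returns
#' the window-clipped original.
#'
#' @inheritParams normalize_intensity
#' @return A [scalar_volume()] in intensity units.
#' @export
denormalize_intensity <- function(volume, window = c(-1000, 1000)) {
  stopifnot(inherits(volume, "scalar_volume"))
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be a finite pair with min < max", call. = FALSE)
  vals <- (volume$values + 1) / 2 * (window[2] - window[1]) + window[1]
  scalar_volume(vals, grid = volume$grid)
}
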