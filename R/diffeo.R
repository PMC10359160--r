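#' Exponentiate a stationary velocity field (scaling and squaring)
#'
#' Converts the raw network output, interpreted as a stationary velocity field,
#' into a displacement field via the group exponential: the velocity is scaled
#' by `2^-n_steps` and self-composed `n_steps` times,
#' `u[k+1](p) = u[k](p) + u[k](p + u[k](p))` with trilinear interpolation.
#' For moderate velocities this construction is diffeomorphic: topology is
#' preserved and contours cannot fold or tear.
#'
#' @param v a [velocity_field()] (mm).
#' @param n_steps number of squaring steps (default 7).
#' @return A [displacement_field()] on the same grid.
#' @export
integrate_velocity <- function(v, n_steps = 7L) {
  stopifnot(inherits(v, "velocity_field"))
  n_steps <- as.integer(n_steps)
  if (length(n_steps) != 1L || is.na(n_steps) || n_steps < 1L)
    stop("n_steps must be a positive integer", call. = FALSE)
  u <- cpp_integrate_velocity(v$vectors, v$grid$shape, v$grid$spacing, n_steps)
  displacement_field(u, grid = v$grid)
}

# per-axis finite difference of a 3D array in physical units:
# central in the interior, one-sided at the borders
fd_axis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  idx <- function(i) {
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- i
    arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
  out <- array(0, d)
  asg <- function(i, val) {
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- i
    out[ix[[1]], ix[[2]], ix[[3]]] <<- val
  }
  asg(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
  asg(1L, (idx(2L) - idx(1L)) / h)
  asg(n, (idx(n) - idx(n - 1L)) / h)
  out
}

#' Jacobian determinant map of a displacement field
#'
#' Computes `det(I + grad u)` at every voxel, the Jacobian determinant of the
#' deformation `f(p) = p + u(p)`. Gradients use central differences in
#' physical units (mm/mm) in the interior and one-sided differences at the
#' border. A value of 1 means locally volume-preserving; values at or below 0
#' mean folding (local loss of invertibility).
#'
#' @param dvf a [displacement_field()].
#' @return A [scalar_volume()] of determinants on the same grid.
#' @export
jacobian_determinant <- function(dvf) {
  stopifnot(inherits(dvf, "displacement_field"))
  g <- dvf$grid
  if (any(g$shape < 3L))
    stop("jacobian_determinant needs at least 3 voxels per axis", call. = FALSE)
  J <- vector("list", 9)
  k <- 1
  for (comp in 1:3) {
    for (axis in 1:3) {
      J[[k]] <- fd_axis(dvf$vectors[, , , comp], axis, g$spacing[axis])
      if (comp == axis) J[[k]] <- J[[k]] + 1
      k <- k + 1
    }
  }
  # rows = components, cols = derivative axes: J[(r-1)*3 + c]
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  scalar_volume(det, grid = g)
}

interior_indices <- function(shape) {
  lapply(shape, function(n) 2:(n - 1))
}

#' Fraction of folded voxels of a displacement field
#'
#' Fraction of interior voxels (one-voxel border excluded, where one-sided
#' differences are less reliable) whose Jacobian determinant is at or below
#' zero. A diffeomorphic field has folding fraction 0.
#'
#' @param dvf a [displacement_field()].
#' @param region optional [binary_mask()] restricting the statistic.
#' @return A number in `[0, 1]`.
#' @export
folding_fraction <- function(dvf, region = NULL) {
  det <- jacobian_determinant(dvf)$values
  ii <- interior_indices(dim(det))
  keep <- array(FALSE, dim(det))
  keep[ii[[1]], ii[[2]], ii[[3]]] <- TRUE
  if (!is.null(region)) {
    stopifnot(inherits(region, "binary_mask"))
    stop_if_grid_mismatch(dvf$grid, region$grid, "dvf and region")
    keep <- keep & region$values
  }
  n <- sum(keep)
  if (n == 0L) return(0)
  sum(det[keep] <= 0) / n
}
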