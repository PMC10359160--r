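#' Loss term weights of the generator objective
#'
#' The generator minimizes
#' `adversarial + lambda1 * image similarity + lambda2 * contrast fidelity +
#' lambda3 * smoothness`. The reconstruction terms dominate by default
#' (Pix2Pix-style weighting); all three weights are tunable.
#'
#' @param lambda1 weight of the image similarity (L1) term.
#' @param lambda2 weight of the contrast fidelity term.
#' @param lambda3 weight of the curvature smoothness term.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 100, lambda3 = 1) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and nonnegative", call. = FALSE)
  structure(as.list(w), class = "loss_weights")
}

#' Soft contrast window
#'
#' Parameters of the differentiable window/level display mapping
#' `I_out = c / (1 + exp(-(I_in - a) / b))`: `a` is the sigmoid center (HU),
#' `b` the width (HU), `c` the output scale. The defaults (500, 500, 3000)
#' mimic the lung window; the mapping operates on the stored intensity scale.
#'
#' @param a sigmoid center (HU).
#' @param b sigmoid width (HU), > 0.
#' @param c output scale, > 0.
#' @return An object of class `contrast_window`.
#' @export
contrast_window <- function(a = 500, b = 500, c = 3000) {
  if (!is.finite(a) || !is.finite(b) || !is.finite(c) || b <= 0 || c <= 0)
    stop("contrast window requires finite a and positive b, c", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "contrast_window")
}

soft_contrast_values <- function(x, w) {
  w$c / (1 + exp(-(x - w$a) / w$b))
}

# derivative of the soft contrast mapping w.r.t. the input intensity
soft_contrast_slope <- function(x, w) {
  s <- 1 / (1 + exp(-(x - w$a) / w$b))
  (w$c / w$b) * s * (1 - s)
}

#' Apply the soft contrast window to a volume
#'
#' Smooth, strictly monotone mapping of intensities into `(0, c)`; the
#' differentiable analogue of the window/level display used to inspect lung
#' detail.
#'
#' @param volume a [scalar_volume()].
#' @param w a [contrast_window()].
#' @return A [scalar_volume()].
#' @export
soft_contrast <- function(volume, w = contrast_window()) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(w, "contrast_window"))
  scalar_volume(soft_contrast_values(volume$values, w), grid = volume$grid)
}

region_values <- function(arr, region, grid) {
  if (is.null(region)) return(as.numeric(arr))
  stopifnot(inherits(region, "binary_mask"))
  stop_if_grid_mismatch(grid, region$grid, "volume and region")
  arr[region$values]
}

#' Image similarity loss (mean absolute difference)
#'
#' L1 loss between the warped source and the target, optionally restricted to
#' a region.
#'
#' @param warped,target [scalar_volume()]s on the same grid.
#' @param region optional [binary_mask()].
#' @return Nonnegative scalar.
#' @export
image_similarity_loss <- function(warped, target, region = NULL) {
  stopifnot(inherits(warped, "scalar_volume"), inherits(target, "scalar_volume"))
  stop_if_grid_mismatch(warped$grid, target$grid, "warped and target")
  d <- region_values(abs(warped$values - target$values), region, warped$grid)
  if (length(d) == 0L) stop("empty comparison region", call. = FALSE)
  mean(d)
}

#' Contrast fidelity loss
#'
#' L1 loss between the soft-contrast-windowed warped source and target. The
#' sigmoid window amplifies discrepancies of features visible in the chosen
#' display window and compresses those far outside it.
#'
#' @inheritParams image_similarity_loss
#' @param w a [contrast_window()].
#' @return Nonnegative scalar.
#' @export
contrast_fidelity_loss <- function(warped, target, w = contrast_window(),
                                   region = NULL) {
  image_similarity_loss(soft_contrast(warped, w), soft_contrast(target, w),
                        region)
}

# interior 6-neighbor Laplacian in physical units; border voxels are zero
lap3 <- function(arr, spacing) {
  d <- dim(arr)
  out <- array(0, d)
  i1 <- 2:(d[1] - 1); i2 <- 2:(d[2] - 1); i3 <- 2:(d[3] - 1)
  out[i1, i2, i3] <-
    (arr[i1 + 1, i2, i3] - 2 * arr[i1, i2, i3] + arr[i1 - 1, i2, i3]) / spacing[1]^2 +
    (arr[i1, i2 + 1, i3] - 2 * arr[i1, i2, i3] + arr[i1, i2 - 1, i3]) / spacing[2]^2 +
    (arr[i1, i2, i3 + 1] - 2 * arr[i1, i2, i3] + arr[i1, i2, i3 - 1]) / spacing[3]^2
  out
}

#' Second-order curvature smoothness term
#'
#' Mean over interior voxels of the summed squared 6-neighbor Laplacian of
#' each field component (physical spacing aware). Affine fields — including
#' rigid motions — incur zero penalty, so the term penalizes curvature of the
#' deformation, not the deformation itself.
#'
#' @param field a [displacement_field()] or [velocity_field()].
#' @return Nonnegative scalar.
#' @export
curvature_regularizer <- function(field) {
  stopifnot(inherits(field, "displacement_field") || inherits(field, "velocity_field"))
  g <- field$grid
  if (any(g$shape < 3L))
    stop("curvature_regularizer needs at least 3 voxels per axis", call. = FALSE)
  n_int <- prod(g$shape - 2)
  total <- 0
  for (comp in 1:3) {
    l <- lap3(field$vectors[, , , comp], g$spacing)
    total <- total + sum(l^2)
  }
  total / n_int
}

#' Adversarial losses from discriminator score maps
#'
#' Binary cross-entropy over patchwise probability score maps (post-sigmoid).
#' The discriminator is trained to score real pairs as 1 and fake pairs as 0;
#' the generator to have its fakes scored as 1.
#'
#' @param disc_real_score,disc_fake_score numeric arrays of probabilities in
#'   `(0, 1)`.
#' @return A list with `generator_term` and `discriminator_term`.
#' @export
adversarial_losses <- function(disc_real_score, disc_fake_score) {
  r <- pmin(pmax(as.numeric(disc_real_score), 1e-12), 1 - 1e-12)
  f <- pmin(pmax(as.numeric(disc_fake_score), 1e-12), 1 - 1e-12)
  if (anyNA(r) || anyNA(f)) stop("score maps must be finite", call. = FALSE)
  list(generator_term = mean(-log(f)),
       discriminator_term = mean(-log(r)) + mean(-log(1 - f)))
}

#' Total generator objective
#'
#' `adv + lambda1 * sim + lambda2 * fid + lambda3 * smooth`.
#'
#' @param adv,sim,fid,smooth the four loss terms.
#' @param weights a [loss_weights()].
#' @return Scalar.
#' @export
generator_total_loss <- function(adv, sim, fid, smooth, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  terms <- c(adv, sim, fid, smooth)
  if (any(!is.finite(terms))) stop("loss terms must be finite", call. = FALSE)
  adv + weights$lambda1 * sim + weights$lambda2 * fid + weights$lambda3 * smooth
}
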