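test_that("soft contrast hits its closed-form landmarks", {
  w <- contrast_window()          # a = 500, b = 500, c = 3000
  vol <- scalar_volume(array(c(500, 1e7, -1e7, 1000, 0, 250, 750, 500),
                             c(2, 2, 2)))
  out <- soft_contrast(vol, w)
  expect_equal(out$values[1, 1, 1], 1500)                       # midpoint c/2
  expect_equal(out$values[2, 1, 1], 3000)                       # upper asymptote
  expect_equal(out$values[1, 2, 1], 0)                          # lower asymptote
  expect_equal(out$values[2, 2, 1], 3000 * exp(1) / (1 + exp(1)),
               tolerance = 1e-9)                                # a + b
  expect_error(contrast_window(b = -1), "positive")
})

test_that("soft contrast is strictly monotone with outputs in (0, c)", {
  set.seed(1)
  x <- sort(runif(200, -2000, 3000))
  vol <- scalar_volume(array(x, c(50, 2, 2)))
  out <- soft_contrast(vol, contrast_window())$values
  expect_true(all(diff(as.numeric(out)) > 0))
  expect_true(all(out > 0 & out < 3000))
})

test_that("image similarity loss is a plain mean absolute difference", {
  a <- scalar_volume(array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2)))
  b <- scalar_volume(array(c(2, 2, 5, 4, 1, 9, 7, 0), c(2, 2, 2)))
  expect_equal(image_similarity_loss(a, a), 0)
  expect_equal(image_similarity_loss(a, b), mean(c(1, 0, 2, 0, 4, 3, 0, 8)))
  off <- scalar_volume(a$values - 13.5, grid = a$grid)
  expect_equal(image_similarity_loss(a, off), 13.5)
  expect_error(image_similarity_loss(a, random_volume(c(3, 3, 3))), "same grid")
})

test_that("contrast fidelity weights window-center differences over far-tail ones", {
  w <- contrast_window()
  a <- scalar_volume(array(-1500, c(4, 4, 4)))
  b <- scalar_volume(array(-1400, c(4, 4, 4)))
  far <- contrast_fidelity_loss(a, b, w) / image_similarity_loss(a, b)
  # near the window center the sigmoid slope is about c/(4b)
  a2 <- scalar_volume(array(499, c(4, 4, 4)))
  b2 <- scalar_volume(array(501, c(4, 4, 4)))
  ctr <- contrast_fidelity_loss(a2, b2, w) / image_similarity_loss(a2, b2)
  expect_equal(ctr, 3000 / (4 * 500), tolerance = 1e-4)
  expect_lt(far, ctr / 10)   # far below the window the mapping compresses
  expect_equal(contrast_fidelity_loss(a, a, w), 0)
})

test_that("contrast fidelity never exceeds the sigmoid slope bound", {
  set.seed(2)
  w <- contrast_window()
  for (r in 1:20) {
    a <- random_volume(c(5, 5, 5), lo = -1500, hi = 2000)
    b <- random_volume(c(5, 5, 5), lo = -1500, hi = 2000)
    expect_lte(contrast_fidelity_loss(a, b, w),
               (w$c / (4 * w$b)) * image_similarity_loss(a, b) + 1e-9)
  }
})

test_that("curvature term vanishes on affine fields and measures curvature", {
  g <- volume_grid(c(8, 8, 8), spacing = c(1, 1, 1))
  expect_equal(curvature_regularizer(zero_displacement(g)), 0)
  co <- grid_coordinates(g)
  A <- matrix(c(0.3, -0.1, 0.2, 0.5, 0.4, -0.2, 0.1, 0, 0.25), 3, 3)
  affine <- array(c(A[1, 1] * co$x + A[1, 2] * co$y + A[1, 3] * co$z + 4,
                    A[2, 1] * co$x + A[2, 2] * co$y + A[2, 3] * co$z - 2,
                    A[3, 1] * co$x + A[3, 2] * co$y + A[3, 3] * co$z + 1),
                  c(g$shape, 3))
  expect_lt(curvature_regularizer(displacement_field(affine, grid = g)), 1e-12)
  quad <- array(0, c(g$shape, 3))
  quad[, , , 1] <- co$x^2
  expect_equal(curvature_regularizer(displacement_field(quad, grid = g)), 4)
  # adding an affine field changes nothing
  both <- displacement_field(quad + affine, grid = g)
  expect_equal(curvature_regularizer(both), 4, tolerance = 1e-9)
})

test_that("adversarial losses follow binary cross-entropy closed forms", {
  perfect <- adversarial_losses(array(1, c(2, 2)), array(0, c(2, 2)))
  expect_lt(perfect$discriminator_term, 1e-9)
  blind <- adversarial_losses(array(0.5, c(2, 2)), array(0.5, c(2, 2)))
  expect_equal(blind$generator_term, log(2), tolerance = 1e-12)
  expect_equal(blind$discriminator_term, 2 * log(2), tolerance = 1e-12)
})

test_that("the total generator objective is the weighted sum", {
  expect_equal(generator_total_loss(0, 0, 0, 0), 0)
  w1 <- loss_weights(1, 1, 1)
  expect_equal(generator_total_loss(1, 2, 3, 4, w1), 10)
  w2 <- loss_weights(100, 0, 1)
  expect_equal(generator_total_loss(1, 2, 3, 4, w2), 1 + 200 + 4)
  expect_error(loss_weights(-1, 0, 0), "nonnegative")
  expect_error(generator_total_loss(Inf, 0, 0, 0), "finite")
})

test_that("the training-path curvature kernel agrees with the public loss", {
  set.seed(3)
  g <- volume_grid(c(10, 10, 10), spacing = c(2.5, 2, 1.5))
  v <- random_smooth_velocity(g, max_mm = 8)
  cg <- dvfsynth:::cpp_curvature_grad(v$vectors, g$shape, g$spacing)
  expect_equal(cg$value, curvature_regularizer(v), tolerance = 1e-12)
  # gradient against central differences at a few random interior voxels
  eps <- 1e-5
  for (probe in 1:6) {
    idx <- sample(length(v$vectors), 1)
    vp <- v$vectors; vp[idx] <- vp[idx] + eps
    vm <- v$vectors; vm[idx] <- vm[idx] - eps
    num <- (curvature_regularizer(velocity_field(vp, grid = g)) -
            curvature_regularizer(velocity_field(vm, grid = g))) / (2 * eps)
    expect_lt(abs(cg$grad[idx] - num), 1e-6 * max(1, abs(num)))
  }
})
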