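test_that("generator output obeys the shape contract and is deterministic", {
  set.seed(1)
  gen <- init_generator(generator_config(levels = 3, base_channels = 2,
                                         channel_cap = 8))
  patch <- scalar_volume(array(runif(8^3, -1, 1), c(8, 8, 8)))
  v1 <- generator_forward(gen, patch)
  v2 <- generator_forward(gen, patch)
  expect_equal(dim(v1$vectors), c(8L, 8L, 8L, 3L))
  expect_true(all(is.finite(v1$vectors)))
  expect_identical(v1$vectors, v2$vectors)
  bad <- scalar_volume(array(0, c(6, 8, 8)))
  expect_error(generator_forward(gen, bad), "divisible")
})

test_that("a 64-voxel patch is rejected by a 7-level generator", {
  set.seed(1)
  gen <- init_generator(generator_config(levels = 7, base_channels = 2,
                                         channel_cap = 4))
  patch <- scalar_volume(array(0, c(64, 64, 64)))
  expect_error(generator_forward(gen, patch), "divisible by 2\\^\\(levels-1\\) = 64")
})

test_that("generator backpropagation matches numerical gradients", {
  set.seed(21)
  cfg <- generator_config(levels = 2, base_channels = 2, channel_cap = 4,
                          vel_scale = 1)
  gen <- init_generator(cfg)
  x <- array(runif(4^3, -1, 1), c(4, 4, 4, 1))
  W <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  loss_of <- function(params) {
    g2 <- gen
    g2$params <- params
    sum(dvfsynth:::gen_fwd(g2, x)$v_raw * W)
  }
  fwd <- dvfsynth:::gen_fwd(gen, x, keep_cache = TRUE)
  grads <- dvfsynth:::gen_bwd(gen, fwd$cache, W)
  eps <- 1e-6
  for (nm in c("enc1.w", "enc1.g", "enc1.be", "enc2.w", "dec1.w", "dec1.b",
               "final.w", "final.b")) {
    idx <- sample(length(gen$params[[nm]]), 1)
    pp <- gen$params
    pp[[nm]][idx] <- pp[[nm]][idx] + eps
    pm <- gen$params
    pm[[nm]][idx] <- pm[[nm]][idx] - eps
    num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(grads[[nm]][idx], num, tolerance = 1e-4,
                 label = sprintf("analytic gradient of %s[%d]", nm, idx))
  }
})

test_that("discriminator backpropagation matches numerical gradients", {
  set.seed(22)
  cfg <- discriminator_config(layers = 2, base_channels = 2, channel_cap = 4)
  disc <- init_discriminator(cfg)
  x <- array(runif(2 * 8^3, -1, 1), c(8, 8, 8, 2))
  fwd <- dvfsynth:::disc_fwd(disc, x, keep_cache = TRUE)
  W <- array(rnorm(length(fwd$logits)), dim(fwd$logits))
  loss_of <- function(params, xx = x) {
    d2 <- disc
    d2$params <- params
    sum(dvfsynth:::disc_fwd(d2, xx)$logits * W)
  }
  bwd <- dvfsynth:::disc_bwd(disc, fwd$cache, W)
  eps <- 1e-6
  for (nm in c("d1.w", "d2.b", "out.w")) {
    idx <- sample(length(disc$params[[nm]]), 1)
    pp <- disc$params
    pp[[nm]][idx] <- pp[[nm]][idx] + eps
    pm <- disc$params
    pm[[nm]][idx] <- pm[[nm]][idx] - eps
    num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(bwd$grads[[nm]][idx], num, tolerance = 1e-4)
  }
  # gradient w.r.t. the input (used by the adversarial term)
  idx <- sample(length(x), 1)
  xp <- x; xp[idx] <- xp[idx] + eps
  xm <- x; xm[idx] <- xm[idx] - eps
  num <- (loss_of(disc$params, xp) - loss_of(disc$params, xm)) / (2 * eps)
  expect_equal(bwd$gx[idx], num, tolerance = 1e-4)
})

test_that("patch sampling is reproducible and honors zero augmentation", {
  case <- small_phantom(seed = 1)
  cfg <- desk_train_config(patch_size = 32, shift_range_mm = c(0, 0),
                           rotation_range_deg = c(0, 0),
                           generator = generator_config(levels = 3,
                                                        base_channels = 2))
  set.seed(5)
  p1 <- sample_training_patch(case, cfg)
  set.seed(5)
  p2 <- sample_training_patch(case, cfg)
  expect_identical(p1$source$values, p2$source$values)
  expect_identical(p1$transform, p2$transform)
  # zero ranges: the patch is a plain crop at the drawn corner
  cr <- p1$transform$corner
  expect_equal(p1$source$values,
               case$dct$values[cr[1]:(cr[1] + 31), cr[2]:(cr[2] + 31),
                               cr[3]:(cr[3] + 31)],
               tolerance = 1e-12)
  small <- list(dct = scalar_volume(array(0, c(16, 16, 16))),
                pct = scalar_volume(array(0, c(16, 16, 16))))
  expect_error(sample_training_patch(small, cfg), "smaller than the patch")
})

test_that("rotating a z-symmetric cylinder changes little inside it", {
  g <- volume_grid(c(48, 48, 48), spacing = c(2.5, 2.5, 2.5))
  co <- grid_coordinates(g)
  ctr <- (g$shape - 1) * g$spacing / 2
  r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2)
  vol <- scalar_volume(1000 * exp(-(r / 40)^2), grid = g)  # cylinder-symmetric
  case <- list(dct = vol, pct = vol)
  cfg <- desk_train_config(patch_size = 48,
                           shift_range_mm = c(0, 0),
                           rotation_range_deg = c(10, 10))
  set.seed(3)
  p <- sample_training_patch(case, cfg)
  inside <- r < 40
  err <- abs(p$source$values - vol$values)[inside]
  expect_lt(max(err), 2)   # interpolation error only
})

test_that("a zero final layer synthesizes the input bit-exactly", {
  case <- small_phantom(seed = 1)
  cfg <- desk_train_config()
  set.seed(1)
  gen <- init_generator(cfg$generator)
  gen$params$final.w[] <- 0
  gen$params$final.b[] <- 0
  dct <- couchless_dct(case)
  out <- synthesize(gen, dct, cfg)
  expect_identical(out$sct$values, dct$values)
  expect_true(all(out$dvf$vectors == 0))
})

test_that("synthesized values stay inside the local interpolation hull", {
  case <- small_phantom(seed = 4)
  cfg <- desk_train_config()
  set.seed(2)
  gen <- init_generator(cfg$generator)
  gen$params$final.b[] <- c(0.2, -0.1, 0.3)  # force a nonzero field
  dct <- couchless_dct(case)
  out <- synthesize(gen, dct, cfg)
  h <- interpolation_hull(dct, out$dvf)
  expect_true(all(out$sct$values >= h$lo$values - 1e-9))
  expect_true(all(out$sct$values <= h$hi$values + 1e-9))
  expect_gte(min(out$sct$values), min(dct$values))
  expect_lte(max(out$sct$values), max(dct$values))
})

test_that("patch tiling with cosine blending reproduces full-volume zero fields", {
  case <- phantom_cohort()[[1]]   # 64 voxels > 48 patch: tiling path
  cfg <- desk_train_config()
  set.seed(3)
  gen <- init_generator(cfg$generator)
  gen$params$final.w[] <- 0
  gen$params$final.b[] <- 0
  dct <- couchless_dct(case)
  out <- synthesize(gen, dct, cfg)
  expect_identical(out$sct$values, dct$values)
})

test_that("a training smoke run logs every loss component finitely", {
  cases <- phantom_cohort()[1:2]
  cfg <- desk_train_config(epochs = 2, seed = 11)
  fit <- train_model(cases, cfg)
  h <- fit$history
  expect_equal(nrow(h), 4)  # 2 epochs x 2 cases
  for (col in c("adv", "sim", "fid", "smooth", "total", "d_loss"))
    expect_true(all(is.finite(h[[col]])), label = col)
  expect_true(all(vapply(fit$generator$params,
                         function(p) all(is.finite(p)), logical(1))))
})

test_that("zero loss weights still train on the adversarial term alone", {
  cases <- phantom_cohort()[1:2]
  cfg <- desk_train_config(epochs = 1, seed = 12,
                           weights = loss_weights(0, 0, 0))
  fit <- train_model(cases, cfg)
  expect_true(all(c("sim", "fid", "smooth") %in% names(fit$history)))
  expect_true(all(is.finite(fit$history$sim)))
  expect_equal(fit$history$total, fit$history$adv)
})

test_that("training twice with the same seed reproduces the history exactly", {
  cases <- phantom_cohort()[1:2]
  cfg <- desk_train_config(epochs = 2, seed = 13)
  f1 <- train_model(cases, cfg)
  f2 <- train_model(cases, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator$params, f2$generator$params)
})

test_that("resumed training extends the history without a gap", {
  cases <- phantom_cohort()[1:2]
  f1 <- train_model(cases, desk_train_config(epochs = 2, seed = 14))
  f2 <- train_model(cases, desk_train_config(epochs = 1, seed = 15),
                    resume = f1)
  expect_equal(nrow(f2$history), 6)
  expect_equal(f2$history$step, 1:6)
  expect_equal(f2$history$epoch, c(1, 1, 2, 2, 3, 3))
})

test_that("checkpoints round trip through disk with a metadata sidecar", {
  cases <- phantom_cohort()[1:2]
  fit <- train_model(cases, desk_train_config(epochs = 1, seed = 16))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 16)
  back <- load_checkpoint(path)
  expect_identical(back$generator$params, fit$generator$params)
  expect_error(load_checkpoint(tempfile()), "no checkpoint")
})
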