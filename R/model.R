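#' Generator (3D U-Net) configuration
#'
#' A U-Net with `levels` encoding/decoding levels. Each encoder level applies
#' a 3x3x3 convolution, per-channel normalization and leaky ReLU, then factor-2
#' average pooling; decoder levels upsample (nearest), concatenate the skip
#' connection, and apply convolution/normalization/ReLU. A final 1x1x1
#' convolution emits the three velocity components, scaled by `vel_scale` mm.
#' The output is unbounded (no final activation); its last layer is
#' initialized near zero so an untrained generator predicts a near-identity
#' deformation, as is standard for registration networks.
#'
#' @param levels number of resolution levels (default 7; inputs must have
#'   sides divisible by `2^(levels - 1)`).
#' @param base_channels channels at the finest level (doubled per level).
#' @param channel_cap ceiling on channels per level.
#' @param vel_scale fixed scale (mm) applied to the raw network output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(levels = 7L, base_channels = 16L,
                             channel_cap = 256L, vel_scale = 20) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) stop("levels must be >= 1", call. = FALSE)
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 channel_cap = as.integer(channel_cap),
                 in_channels = 1L, out_channels = 3L,
                 vel_scale = vel_scale),
            class = "generator_config")
}

#' Discriminator (convolutional encoder) configuration
#'
#' Takes the 2-channel conditional pair (source volume, candidate volume) and
#' emits a patchwise real/fake logit map after `layers` conv + leaky ReLU +
#' pool stages and a 1x1x1 projection.
#'
#' @param layers number of downsampling stages (>= 1).
#' @param base_channels channels of the first stage (doubled per stage).
#' @param channel_cap ceiling on channels per stage.
#' @param input_pool if `TRUE`, average-pool the input pair once before the
#'   first convolution, so the discriminator judges half-resolution pairs
#'   (cheaper; used by the desk-scale profile).
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(layers = 4L, base_channels = 32L,
                                 channel_cap = 256L, input_pool = FALSE) {
  layers <- as.integer(layers)
  if (is.na(layers) || layers < 1L) stop("layers must be >= 1", call. = FALSE)
  structure(list(layers = layers, base_channels = as.integer(base_channels),
                 channel_cap = as.integer(channel_cap), in_channels = 2L,
                 input_pool = isTRUE(input_pool)),
            class = "discriminator_config")
}

#' Training configuration
#'
#' All learning hyperparameters: patch size and augmentation ranges, loss
#' weights and contrast window, integration steps, optimizer settings, and
#' the master seed. The 128-voxel patch with 7 levels is the full-fidelity
#' default; tests and examples use 48-voxel patches with 5 levels so a full
#' train/evaluate cycle runs on one CPU in minutes.
#'
#' @param patch_size cubic patch side (voxels); must be divisible by
#'   `2^(levels - 1)` of the generator.
#' @param shift_range_mm augmentation shift range, mm.
#' @param rotation_range_deg augmentation rotation range about the
#'   superior-inferior axis, degrees.
#' @param weights a [loss_weights()].
#' @param contrast a [contrast_window()].
#' @param n_integration_steps scaling-and-squaring steps (default 7).
#' @param epochs,batch_size,learning_rate_g,learning_rate_d optimizer settings.
#' @param normalization_window HU window mapped to `[-1, 1]` for network
#'   input.
#' @param generator a [generator_config()].
#' @param discriminator a [discriminator_config()].
#' @param seed master RNG seed; all training randomness flows from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(patch_size = 128L,
                         shift_range_mm = c(-20, 20),
                         rotation_range_deg = c(-10, 10),
                         weights = loss_weights(),
                         contrast = contrast_window(),
                         n_integration_steps = 7L,
                         epochs = 30L, batch_size = 1L,
                         learning_rate_g = 1e-3, learning_rate_d = 1e-3,
                         normalization_window = c(-1000, 1000),
                         generator = generator_config(),
                         discriminator = discriminator_config(),
                         seed = 1L) {
  stopifnot(inherits(weights, "loss_weights"), inherits(contrast, "contrast_window"),
            inherits(generator, "generator_config"),
            inherits(discriminator, "discriminator_config"))
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (shift_range_mm[1] > shift_range_mm[2] ||
      rotation_range_deg[1] > rotation_range_deg[2])
    stop("augmentation ranges must be well ordered", call. = FALSE)
  patch_size <- as.integer(patch_size)
  div <- 2L^(generator$levels - 1L)
  if (patch_size %% div != 0L || patch_size < 2L * div)
    stop(sprintf(paste0("patch_size must be divisible by 2^(levels-1) = %d ",
                        "and leave at least 2 voxels at the coarsest level"),
                 div), call. = FALSE)
  structure(list(patch_size = patch_size, shift_range_mm = shift_range_mm,
                 rotation_range_deg = rotation_range_deg, weights = weights,
                 contrast = contrast,
                 n_integration_steps = as.integer(n_integration_steps),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate_g = learning_rate_g,
                 learning_rate_d = learning_rate_d,
                 normalization_window = normalization_window,
                 generator = generator, discriminator = discriminator,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' The reduced profile used throughout tests and examples: 48-voxel patches,
#' a 5-level generator with 3 base channels, a 3-stage discriminator, and 30
#' epochs, so training completes in minutes on one CPU.
#'
#' @param ... overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
desk_train_config <- function(...) {
  defaults <- list(patch_size = 48L,
                   generator = generator_config(levels = 5L, base_channels = 3L,
                                                channel_cap = 32L),
                   discriminator = discriminator_config(layers = 3L,
                                                        base_channels = 8L,
                                                        channel_cap = 32L,
                                                        input_pool = TRUE),
                   epochs = 30L)
  do.call(train_config, modifyList(defaults, list(...)))
}

gen_channels <- function(cfg) {
  pmin(cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L), cfg$channel_cap)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Initialize a generator
#'
#' Weights use He initialization; the final velocity projection is initialized
#' near zero so the untrained network predicts a near-identity deformation.
#' Drawing uses the current RNG state (seed it for reproducibility).
#'
#' @param cfg a [generator_config()].
#' @return An object of class `dvf_generator`.
#' @export
init_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  ch <- gen_channels(cfg)
  L <- cfg$levels
  p <- list()
  cin <- cfg$in_channels
  for (k in seq_len(L)) {
    p[[sprintf("enc%d.w", k)]] <- he_init(c(3, 3, 3, cin, ch[k]), 27 * cin)
    p[[sprintf("enc%d.b", k)]] <- numeric(ch[k])
    p[[sprintf("enc%d.g", k)]] <- rep(1, ch[k])
    p[[sprintf("enc%d.be", k)]] <- numeric(ch[k])
    cin <- ch[k]
  }
  for (k in rev(seq_len(L - 1))) {
    cin <- ch[k + 1] + ch[k]
    p[[sprintf("dec%d.w", k)]] <- he_init(c(3, 3, 3, cin, ch[k]), 27 * cin)
    p[[sprintf("dec%d.b", k)]] <- numeric(ch[k])
    p[[sprintf("dec%d.g", k)]] <- rep(1, ch[k])
    p[[sprintf("dec%d.be", k)]] <- numeric(ch[k])
  }
  p[["final.w"]] <- array(rnorm(ch[1] * 3, 0, 1e-3), c(ch[1], 3))
  p[["final.b"]] <- numeric(3)
  structure(list(cfg = cfg, params = p), class = "dvf_generator")
}

#' Initialize a discriminator
#'
#' @param cfg a [discriminator_config()].
#' @return An object of class `pair_discriminator`.
#' @export
init_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "discriminator_config"))
  ch <- pmin(cfg$base_channels * 2L^(seq_len(cfg$layers) - 1L), cfg$channel_cap)
  p <- list()
  cin <- cfg$in_channels
  for (k in seq_len(cfg$layers)) {
    p[[sprintf("d%d.w", k)]] <- he_init(c(3, 3, 3, cin, ch[k]), 27 * cin)
    p[[sprintf("d%d.b", k)]] <- numeric(ch[k])
    cin <- ch[k]
  }
  p[["out.w"]] <- array(rnorm(cin, 0, sqrt(1 / cin)), c(cin, 1))
  p[["out.b"]] <- numeric(1)
  structure(list(cfg = cfg, params = p), class = "pair_discriminator")
}

gen_fwd <- function(gen, x, keep_cache = FALSE) {
  p <- gen$params
  L <- gen$cfg$levels
  cache <- if (keep_cache) list(enc = vector("list", L),
                                dec = vector("list", L)) else NULL
  h <- x
  skips <- vector("list", L)
  for (k in seq_len(L)) {
    c1 <- nn_conv3_fwd(h, p[[sprintf("enc%d.w", k)]], p[[sprintf("enc%d.b", k)]])
    c2 <- nn_norm_fwd(c1$y, p[[sprintf("enc%d.g", k)]], p[[sprintf("enc%d.be", k)]])
    c3 <- nn_lrelu_fwd(c2$y)
    skips[[k]] <- c3$y
    if (k < L) {
      c4 <- nn_pool2_fwd(c3$y)
      h <- c4$y
    } else c4 <- NULL
    if (keep_cache) cache$enc[[k]] <- list(conv = c1, norm = c2, act = c3, pool = c4)
  }
  h <- skips[[L]]
  for (k in rev(seq_len(L - 1))) {
    u <- nn_up2_fwd(h)
    cc <- nn_concat_fwd(u$y, skips[[k]])
    c1 <- nn_conv3_fwd(cc$y, p[[sprintf("dec%d.w", k)]], p[[sprintf("dec%d.b", k)]])
    c2 <- nn_norm_fwd(c1$y, p[[sprintf("dec%d.g", k)]], p[[sprintf("dec%d.be", k)]])
    c3 <- nn_lrelu_fwd(c2$y, alpha = 0)   # plain ReLU on the decoding path
    h <- c3$y
    if (keep_cache) cache$dec[[k]] <- list(up = u, cat = cc, conv = c1,
                                           norm = c2, act = c3)
  }
  fin <- nn_conv1_fwd(h, p[["final.w"]], p[["final.b"]])
  if (keep_cache) cache$final <- fin
  list(v_raw = fin$y, cache = cache)
}

gen_bwd <- function(gen, cache, gv_raw) {
  p <- gen$params
  L <- gen$cfg$levels
  g <- list()
  fb <- nn_conv1_bwd(cache$final, gv_raw)
  g[["final.w"]] <- fb$gw
  g[["final.b"]] <- fb$gb
  gh <- fb$gx
  gskip <- vector("list", L)
  for (k in seq_len(L - 1)) {
    dc <- cache$dec[[k]]
    ga <- nn_lrelu_bwd(dc$act, gh)
    nb <- nn_norm_bwd(dc$norm, p[[sprintf("dec%d.g", k)]], ga)
    g[[sprintf("dec%d.g", k)]] <- nb$ggamma
    g[[sprintf("dec%d.be", k)]] <- nb$gbeta
    cb <- nn_conv3_bwd(dc$conv, nb$gx)
    g[[sprintf("dec%d.w", k)]] <- cb$gw
    g[[sprintf("dec%d.b", k)]] <- cb$gb
    sp <- nn_concat_bwd(dc$cat, cb$gx)
    gskip[[k]] <- sp$gb
    gh <- nn_up2_bwd(dc$up, sp$ga)
  }
  gskip[[L]] <- gh
  gdown <- NULL
  for (k in rev(seq_len(L))) {
    ec <- cache$enc[[k]]
    gs <- gskip[[k]]
    if (k < L) gs <- gs + nn_pool2_bwd(ec$pool, gdown)
    ga <- nn_lrelu_bwd(ec$act, gs)
    nb <- nn_norm_bwd(ec$norm, p[[sprintf("enc%d.g", k)]], ga)
    g[[sprintf("enc%d.g", k)]] <- nb$ggamma
    g[[sprintf("enc%d.be", k)]] <- nb$gbeta
    cb <- nn_conv3_bwd(ec$conv, nb$gx, need_gx = k > 1L)
    g[[sprintf("enc%d.w", k)]] <- cb$gw
    g[[sprintf("enc%d.b", k)]] <- cb$gb
    gdown <- cb$gx
  }
  g
}

disc_fwd <- function(disc, x, keep_cache = FALSE) {
  p <- disc$params
  nl <- disc$cfg$layers
  cache <- if (keep_cache) vector("list", nl) else NULL
  h <- x
  if (disc$cfg$input_pool) {
    p0 <- nn_pool2_fwd(h)
    h <- p0$y
    if (keep_cache) cache$input_pool <- p0
  }
  for (k in seq_len(nl)) {
    c1 <- nn_conv3_fwd(h, p[[sprintf("d%d.w", k)]], p[[sprintf("d%d.b", k)]])
    c2 <- nn_lrelu_fwd(c1$y)
    c3 <- nn_pool2_fwd(c2$y)
    h <- c3$y
    if (keep_cache) cache[[k]] <- list(conv = c1, act = c2, pool = c3)
  }
  fin <- nn_conv1_fwd(h, p[["out.w"]], p[["out.b"]])
  if (keep_cache) cache$final <- fin
  list(logits = fin$y, cache = cache)
}

disc_bwd <- function(disc, cache, glogits, need_input_grad = TRUE) {
  p <- disc$params
  nl <- disc$cfg$layers
  g <- list()
  fb <- nn_conv1_bwd(cache$final, glogits)
  g[["out.w"]] <- fb$gw
  g[["out.b"]] <- fb$gb
  gh <- fb$gx
  for (k in rev(seq_len(nl))) {
    ck <- cache[[k]]
    gp <- nn_pool2_bwd(ck$pool, gh)
    ga <- nn_lrelu_bwd(ck$act, gp)
    cb <- nn_conv3_bwd(ck$conv, ga, need_gx = need_input_grad || k > 1L)
    g[[sprintf("d%d.w", k)]] <- cb$gw
    g[[sprintf("d%d.b", k)]] <- cb$gb
    gh <- cb$gx
  }
  if (need_input_grad && disc$cfg$input_pool)
    gh <- nn_pool2_bwd(cache$input_pool, gh)
  list(grads = g, gx = gh)
}

#' Predict a velocity field for a normalized patch
#'
#' Runs the generator on a single-channel normalized volume and returns the
#' three-component stationary velocity field (mm). Deterministic: identical
#' weights and input give identical output.
#'
#' @param gen a `dvf_generator` from [init_generator()] or [train_model()].
#' @param patch a [scalar_volume()] with intensities normalized to `[-1, 1]`,
#'   every side divisible by `2^(levels - 1)`.
#' @return A [velocity_field()] on the patch grid.
#' @export
generator_forward <- function(gen, patch) {
  stopifnot(inherits(gen, "dvf_generator"), inherits(patch, "scalar_volume"))
  d <- patch$grid$shape
  div <- 2L^(gen$cfg$levels - 1L)
  if (any(d %% div != 0L) || any(d < 2L * div))
    stop(sprintf(paste0("patch sides must be divisible by 2^(levels-1) = %d ",
                        "and leave at least 2 voxels at the coarsest level"),
                 div), call. = FALSE)
  x <- array(patch$values, c(d, 1L))
  out <- gen_fwd(gen, x)
  velocity_field(out$v_raw * gen$cfg$vel_scale, grid = patch$grid)
}

#' Sample an augmented training patch pair
#'
#' Draws a random cubic patch with a random in-plane rotation about the
#' superior-inferior axis and a random millimetre shift, applied identically
#' to the source and target volume so the pair stays aligned. Uses the
#' current RNG state; the returned transform record makes the draw
#' reproducible.
#'
#' @param case a list with [scalar_volume()]s `dct` and `pct` on a shared
#'   grid (e.g. a `phantom_case`).
#' @param cfg a [train_config()].
#' @return A list with `source`, `target` ([scalar_volume()] patches) and
#'   `transform` (corner index, shift in mm, angle in degrees).
#' @export
sample_training_patch <- function(case, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  dct <- case$dct
  pct <- case$pct
  stopifnot(inherits(dct, "scalar_volume"), inherits(pct, "scalar_volume"))
  stop_if_grid_mismatch(dct$grid, pct$grid, "dct and pct")
  g <- dct$grid
  ps <- cfg$patch_size
  if (any(g$shape < ps))
    stop("volumes are smaller than the patch size", call. = FALSE)
  corner <- vapply(g$shape, function(n) sample.int(n - ps + 1L, 1L), integer(1))
  shift <- runif(3, cfg$shift_range_mm[1], cfg$shift_range_mm[2])
  angle <- runif(1, cfg$rotation_range_deg[1], cfg$rotation_range_deg[2])
  q <- base_voxel_coords(c(ps, ps, ps))
  # rotate patch coordinates about the patch center (z axis), then shift (mm)
  cx <- (ps - 1) / 2
  th <- angle * pi / 180
  rx <- cx + cos(th) * (q$x - cx) - sin(th) * (q$y - cx) * g$spacing[2] / g$spacing[1]
  ry <- cx + sin(th) * (q$x - cx) * g$spacing[1] / g$spacing[2] + cos(th) * (q$y - cx)
  qx <- rx + (corner[1] - 1) + shift[1] / g$spacing[1]
  qy <- ry + (corner[2] - 1) + shift[2] / g$spacing[2]
  qz <- q$z + (corner[3] - 1) + shift[3] / g$spacing[3]
  pg <- volume_grid(c(ps, ps, ps), g$spacing,
                    g$origin + (corner - 1) * g$spacing)
  take <- function(vol) {
    vals <- cpp_sample3d(vol$values, g$shape, qx, qy, qz, TRUE)
    scalar_volume(array(vals, c(ps, ps, ps)), grid = pg)
  }
  list(source = take(dct), target = take(pct),
       transform = list(corner = corner, shift_mm = shift, angle_deg = angle))
}

# warp patch HU values with a displacement, returning the warped values and
# the spatial intensity gradient (HU/mm) at the sampled positions
warp_with_grad <- function(values, grid, u) {
  q <- base_voxel_coords(grid$shape)
  sg <- cpp_sample3d_grad(values, grid$shape,
                          q$x + u[, , , 1] / grid$spacing[1],
                          q$y + u[, , , 2] / grid$spacing[2],
                          q$z + u[, , , 3] / grid$spacing[3])
  list(warped = array(sg$value, grid$shape),
       gx = array(sg$gx, grid$shape) / grid$spacing[1],
       gy = array(sg$gy, grid$shape) / grid$spacing[2],
       gz = array(sg$gz, grid$shape) / grid$spacing[3])
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train the generator-discriminator pair
#'
#' Alternating adversarial training: per case and epoch, one generator update
#' against the full objective (adversarial + weighted image similarity,
#' contrast fidelity, and curvature smoothness, with the warped image produced
#' through velocity integration and trilinear warping inside the loss path)
#' and one discriminator update on the conditional real/fake pairs. Couch
#' removal and intensity normalization are applied once per case up front.
#' All randomness flows from `cfg$seed`; a fixed seed reproduces the history
#' exactly.
#'
#' @param dataset nonempty list of cases (each with `dct` and `pct`
#'   [scalar_volume()]s, e.g. from [make_dataset()]).
#' @param cfg a [train_config()].
#' @param resume optional result of a previous [train_model()] call to
#'   continue from (its weights, optimizer state and history are extended).
#' @return A list of class `dvfsynth_fit` with `generator`, `discriminator`,
#'   `history` (one row per generator step with every loss component), and
#'   `config`.
#' @export
train_model <- function(dataset, cfg, resume = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  if (!is.list(dataset) || length(dataset) == 0L)
    stop("dataset must be a nonempty list of cases", call. = FALSE)
  set.seed(cfg$seed)
  if (is.null(resume)) {
    gen <- init_generator(cfg$generator)
    disc <- init_discriminator(cfg$discriminator)
    opt_g <- adam_init(gen$params)
    opt_d <- adam_init(disc$params)
    history <- NULL
    epoch0 <- 0L
  } else {
    stopifnot(inherits(resume, "dvfsynth_fit"))
    gen <- resume$generator
    disc <- resume$discriminator
    opt_g <- resume$opt_g
    opt_d <- resume$opt_d
    history <- resume$history
    epoch0 <- if (is.null(history)) 0L else max(history$epoch)
  }
  win <- cfg$normalization_window
  half <- (win[2] - win[1]) / 2
  prep <- lapply(dataset, function(case) {
    body <- segment_body(case$dct)
    dct <- remove_couch(case$dct, body)
    pct <- remove_couch(case$pct, segment_body(case$pct))
    list(dct = dct, pct = pct)
  })
  lam <- cfg$weights
  w <- cfg$contrast
  rows <- list()
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    for (ci in seq_along(prep)) {
      step <- step + 1L
      patch <- sample_training_patch(prep[[ci]], cfg)
      pg <- patch$source$grid
      x_n <- array(normalize_values(patch$source$values, win), c(pg$shape, 1L))
      fwd <- gen_fwd(gen, x_n, keep_cache = TRUE)
      v <- fwd$v_raw * gen$cfg$vel_scale
      u <- integrate_velocity(velocity_field(v, grid = pg),
                              cfg$n_integration_steps)$vectors
      wg <- warp_with_grad(patch$source$values, pg, u)
      target <- patch$target$values
      nvox <- prod(pg$shape)

      diff <- wg$warped - target
      sim <- mean(abs(diff))
      d_sim <- sign(diff) / nvox

      sc_w <- soft_contrast_values(wg$warped, w)
      sc_t <- soft_contrast_values(target, w)
      fid <- mean(abs(sc_w - sc_t))
      d_fid <- sign(sc_w - sc_t) * soft_contrast_slope(wg$warped, w) / nvox

      cg <- cpp_curvature_grad(v, pg$shape, pg$spacing)
      smooth <- cg$value
      g_smooth <- cg$grad

      warped_n <- normalize_values(wg$warped, win)
      in_window <- wg$warped > win[1] & wg$warped < win[2]
      fake_in <- array(c(x_n, warped_n), c(pg$shape, 2L))
      dfake <- disc_fwd(disc, fake_in, keep_cache = TRUE)
      nscore <- length(dfake$logits)
      adv <- mean(softplus(-dfake$logits))          # BCE(fake -> 1)
      g_logit_adv <- array(-sigmoid(-dfake$logits) / nscore, dim(dfake$logits))
      adv_b <- disc_bwd(disc, dfake$cache, g_logit_adv)
      d_adv <- adv_b$gx[, , , 2] * in_window / half

      d_warped <- d_adv + lam$lambda1 * d_sim + lam$lambda2 * d_fid
      # dL/du, then dL/dv under the first-order (identity) approximation of
      # the exponential's derivative, plus the exact smoothness gradient
      gv <- array(0, dim(v))
      gv[, , , 1] <- d_warped * wg$gx + lam$lambda3 * g_smooth[, , , 1]
      gv[, , , 2] <- d_warped * wg$gy + lam$lambda3 * g_smooth[, , , 2]
      gv[, , , 3] <- d_warped * wg$gz + lam$lambda3 * g_smooth[, , , 3]
      g_gen <- gen_bwd(gen, fwd$cache, gv * gen$cfg$vel_scale)

      total <- generator_total_loss(adv, sim, fid, smooth, lam)
      if (!is.finite(total))
        stop(sprintf(paste0("non-finite generator loss at epoch %d, step %d ",
                            "(adv=%g sim=%g fid=%g smooth=%g); aborting"),
                     epoch0 + epoch, step, adv, sim, fid, smooth), call. = FALSE)
      up <- adam_step(gen$params, g_gen, opt_g, cfg$learning_rate_g)
      gen$params <- up$params
      opt_g <- up$state

      # discriminator update on the real pair and the (detached) fake pair;
      # the fake-pair forward pass is reused since the weights are unchanged
      target_n <- normalize_values(target, win)
      real_in <- array(c(x_n, target_n), c(pg$shape, 2L))
      dreal <- disc_fwd(disc, real_in, keep_cache = TRUE)
      d_loss <- mean(softplus(-dreal$logits)) + mean(softplus(dfake$logits))
      if (!is.finite(d_loss))
        stop(sprintf("non-finite discriminator loss at epoch %d, step %d",
                     epoch0 + epoch, step), call. = FALSE)
      gr <- array(-sigmoid(-dreal$logits) / nscore, dim(dreal$logits))
      gf <- array(sigmoid(dfake$logits) / nscore, dim(dfake$logits))
      gb_r <- disc_bwd(disc, dreal$cache, gr, need_input_grad = FALSE)
      gb_f <- disc_bwd(disc, dfake$cache, gf, need_input_grad = FALSE)
      g_disc <- Map(`+`, gb_r$grads[names(disc$params)],
                    gb_f$grads[names(disc$params)])
      upd <- adam_step(disc$params, g_disc, opt_d, cfg$learning_rate_d)
      disc$params <- upd$params
      opt_d <- upd$state

      rows[[length(rows) + 1L]] <- data.frame(
        epoch = epoch0 + epoch, step = step, case = ci,
        adv = adv, sim = sim, fid = fid, smooth = smooth,
        total = total, d_loss = d_loss)
    }
  }
  new_hist <- do.call(rbind, rows)
  if (!is.null(new_hist) && !is.null(history)) {
    new_hist$step <- new_hist$step + max(history$step)
    new_hist <- rbind(history, new_hist)
  } else if (is.null(new_hist)) new_hist <- history
  structure(list(generator = gen, discriminator = disc, history = new_hist,
                 config = cfg, opt_g = opt_g, opt_d = opt_d),
            class = "dvfsynth_fit")
}

#' @export
print.dvfsynth_fit <- function(x, ...) {
  cat(sprintf("<dvfsynth_fit> %d generator steps, final total loss %.3f\n",
              nrow(x$history), x$history$total[nrow(x$history)]))
  invisible(x)
}

# Hann window weights for cosine-blended patch tiling
hann1 <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)

predict_velocity_full <- function(gen, vol_n, patch_size) {
  g <- vol_n$grid
  d <- g$shape
  div <- 2L^(gen$cfg$levels - 1L)
  if (all(d <= patch_size)) {
    pad <- (div - d %% div) %% div
    if (all(pad == 0L)) {
      v <- generator_forward(gen, vol_n)$vectors
    } else {
      padded <- array(0, d + pad)
      padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol_n$values
      # replicate the last plane into the padding
      if (pad[1] > 0) padded[(d[1] + 1):(d[1] + pad[1]), , ] <-
          padded[rep(d[1], pad[1]), , ]
      if (pad[2] > 0) padded[, (d[2] + 1):(d[2] + pad[2]), ] <-
          padded[, rep(d[2], pad[2]), ]
      if (pad[3] > 0) padded[, , (d[3] + 1):(d[3] + pad[3])] <-
          padded[, , rep(d[3], pad[3])]
      pv <- scalar_volume(padded, spacing = g$spacing, origin = g$origin)
      v <- generator_forward(gen, pv)$vectors
      v <- v[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , drop = FALSE]
    }
    return(velocity_field(v, grid = g))
  }
  ps <- rep(as.integer(patch_size), 3L)
  starts <- lapply(1:3, function(a) {
    if (d[a] <= ps[a]) return(1L)
    s <- seq(1L, d[a] - ps[a] + 1L, by = max(1L, ps[a] %/% 2L))
    unique(c(s, d[a] - ps[a] + 1L))
  })
  acc <- array(0, c(d, 3L))
  wacc <- array(0, d)
  wp <- outer(outer(hann1(ps[1]), hann1(ps[2])), hann1(ps[3]))
  dim(wp) <- ps
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx:(sx + ps[1] - 1); iy <- sy:(sy + ps[2] - 1); iz <- sz:(sz + ps[3] - 1)
    pgrid <- volume_grid(ps, g$spacing,
                         g$origin + (c(sx, sy, sz) - 1) * g$spacing)
    pv <- scalar_volume(vol_n$values[ix, iy, iz, drop = FALSE], grid = pgrid)
    v <- generator_forward(gen, pv)$vectors
    for (c in 1:3) acc[ix, iy, iz, c] <- acc[ix, iy, iz, c] + v[, , , c] * wp
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + wp
  }
  for (c in 1:3) acc[, , , c] <- acc[, , , c] / wacc
  velocity_field(acc, grid = g)
}

#' Synthesize a planning-like CT from a diagnostic CT
#'
#' Predicts a stationary velocity field for the (couch-removed) input volume
#' — full-volume when it fits one patch, otherwise from overlapping patches
#' blended with a cosine window — integrates it into a diffeomorphic
#' displacement field, and warps the original-intensity input. Every
#' synthesized voxel is a trilinear interpolation of input voxels: no
#' intensity is hallucinated, so the Hounsfield calibration is preserved.
#'
#' @param gen a trained `dvf_generator` (or a [train_model()] result).
#' @param dct a couch-removed [scalar_volume()] in HU.
#' @param cfg the [train_config()] (normalization window, patch size,
#'   integration steps).
#' @return A list with `sct` ([scalar_volume()]), `dvf`
#'   ([displacement_field()]), and `velocity` ([velocity_field()]).
#' @export
synthesize <- function(gen, dct, cfg) {
  if (inherits(gen, "dvfsynth_fit")) gen <- gen$generator
  stopifnot(inherits(gen, "dvf_generator"), inherits(dct, "scalar_volume"),
            inherits(cfg, "train_config"))
  vol_n <- normalize_intensity(dct, cfg$normalization_window)
  v <- predict_velocity_full(gen, vol_n, cfg$patch_size)
  if (all(v$vectors == 0)) {
    u <- zero_displacement(dct$grid)
    return(list(sct = dct, dvf = u, velocity = v))
  }
  u <- integrate_velocity(v, cfg$n_integration_steps)
  list(sct = warp(dct, u, interpolation = "linear"), dvf = u, velocity = v)
}

#' Save a fit (or generator) checkpoint
#'
#' Writes the serialized model next to a JSON metadata sidecar
#' (`<path>.json`) holding the seed, configuration, a content hash, and the
#' package version.
#'
#' @param fit a `dvfsynth_fit` from [train_model()].
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "dvfsynth_fit"))
  saveRDS(fit, path)
  meta <- list(
    seed = fit$config$seed,
    epochs_trained = if (is.null(fit$history)) 0L else max(fit$history$epoch),
    steps = if (is.null(fit$history)) 0L else nrow(fit$history),
    config = unclass_config(fit$config),
    checkpoint_md5 = unname(tools::md5sum(path)),
    package_version = as.character(utils::packageVersion("dvfsynth")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_config <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_config) else x
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path path to the `.rds` checkpoint.
#' @return A `dvfsynth_fit`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("no checkpoint at '%s'", path), call. = FALSE)
  fit <- readRDS(path)
  if (!inherits(fit, "dvfsynth_fit"))
    stop(sprintf("'%s' is not a dvfsynth checkpoint", path), call. = FALSE)
  fit
}
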