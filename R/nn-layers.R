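# Minimal tensor layers for the 3D U-Net generator and convolutional
# discriminator. Feature maps are numeric arrays (X, Y, Z, C); every forward
# returns the cache its backward needs. All differentiation is manual.

nn_conv3_fwd <- function(x, w, b) {
  d <- dim(x)
  y <- cpp_conv3_forward(x, d[1:3], d[4], w, b, dim(w)[5])
  list(y = y, x = x, w = w)
}

nn_conv3_bwd <- function(cache, gy, need_gx = TRUE) {
  d <- dim(cache$x)
  r <- cpp_conv3_backward(cache$x, d[1:3], d[4], cache$w, dim(cache$w)[5], gy,
                          need_gx)
  list(gx = r$gx, gw = array(r$gw, dim(cache$w)), gb = r$gb)
}

nn_conv1_fwd <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  ym <- xm %*% w
  ym <- sweep(ym, 2, b, "+")
  list(y = array(ym, c(d[1:3], ncol(w))), xm = xm, w = w)
}

nn_conv1_bwd <- function(cache, gy) {
  d <- dim(gy)
  gm <- matrix(gy, ncol = d[4])
  list(gx = array(gm %*% t(cache$w), c(d[1:3], ncol(cache$xm))),
       gw = crossprod(cache$xm, gm),
       gb = colSums(gm))
}

# per-channel normalization over the spatial dimensions (batch of one)
nn_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  r <- cpp_norm_fwd(x, prod(d[1:3]), d[4], gamma, beta, eps)
  list(y = r$y, xhat = r$xhat, istd = r$istd, dims = d)
}

nn_norm_bwd <- function(cache, gamma, gy) {
  d <- cache$dims
  r <- cpp_norm_bwd(gy, cache$xhat, cache$istd, gamma, prod(d[1:3]), d[4])
  list(gx = r$gx, ggamma = r$ggamma, gbeta = r$gbeta)
}

nn_lrelu_fwd <- function(x, alpha = 0.2) {
  scale <- alpha + (1 - alpha) * (x > 0)
  list(y = x * scale, scale = scale)
}

nn_lrelu_bwd <- function(cache, gy) {
  gy * cache$scale
}

nn_pool2_fwd <- function(x) {
  d <- dim(x)
  stopifnot(all(d[1:3] %% 2 == 0))
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2); o3 <- seq(1, d[3], 2)
  y <- (x[o1, o2, o3, , drop = FALSE]     + x[o1 + 1, o2, o3, , drop = FALSE] +
        x[o1, o2 + 1, o3, , drop = FALSE] + x[o1 + 1, o2 + 1, o3, , drop = FALSE] +
        x[o1, o2, o3 + 1, , drop = FALSE] + x[o1 + 1, o2, o3 + 1, , drop = FALSE] +
        x[o1, o2 + 1, o3 + 1, , drop = FALSE] +
        x[o1 + 1, o2 + 1, o3 + 1, , drop = FALSE]) / 8
  list(y = y, in_dims = d)
}

nn_up2_raw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

nn_pool2_bwd <- function(cache, gy) {
  nn_up2_raw(gy) / 8
}

nn_up2_fwd <- function(x) {
  list(y = nn_up2_raw(x), in_dims = dim(x))
}

nn_up2_bwd <- function(cache, gy) {
  nn_pool2_fwd(gy)$y * 8
}

nn_concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  list(y = array(c(a, b), c(da[1:3], da[4] + db[4])), ca = da[4], cb = db[4])
}

nn_concat_bwd <- function(cache, gy) {
  d <- dim(gy)
  list(ga = gy[, , , seq_len(cache$ca), drop = FALSE],
       gb = gy[, , , cache$ca + seq_len(cache$cb), drop = FALSE])
}

# ---------------------------------------------------------------------------
# Adam over a flat named list of parameter arrays
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
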