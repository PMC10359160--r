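# Independent brute-force oracles, deliberately naive: plain R loops and
# closed forms, sharing no code with the package implementations they check.

oracle_rassd <- function(a, b, region = NULL) {
  av <- as.numeric(a$values)
  bv <- as.numeric(b$values)
  keep <- if (is.null(region)) rep(TRUE, length(av)) else as.logical(region$values)
  s <- 0
  n <- 0
  for (i in which(keep)) {
    s <- s + (av[i] - bv[i])^2
    n <- n + 1
  }
  sqrt(s / n)
}

oracle_dsc <- function(x, y) {
  xv <- as.logical(x$values)
  yv <- as.logical(y$values)
  if (!any(xv) && !any(yv)) return(1)
  2 * sum(xv & yv) / (sum(xv) + sum(yv))
}

# surface extraction by explicit neighbor checks, then a full double loop
oracle_surface <- function(mask) {
  v <- mask$values
  d <- dim(v)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!v[i, j, k]) next
    nb <- c(
      if (i > 1) v[i - 1, j, k] else FALSE,
      if (i < d[1]) v[i + 1, j, k] else FALSE,
      if (j > 1) v[i, j - 1, k] else FALSE,
      if (j < d[2]) v[i, j + 1, k] else FALSE,
      if (k > 1) v[i, j, k - 1] else FALSE,
      if (k < d[3]) v[i, j, k + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_hausdorff <- function(x, y) {
  sa <- oracle_surface(x)
  sb <- oracle_surface(y)
  g <- x$grid
  pa <- sweep(sweep(sa - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  pb <- sweep(sweep(sb - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# a random blobby mask: a few random spheres, <= ~200 foreground voxels
random_small_mask <- function(shape = c(12, 12, 12), spacing = c(2.5, 2.5, 2.5),
                              n_blobs = 2) {
  g <- volume_grid(shape, spacing)
  co <- grid_coordinates(g)
  v <- array(FALSE, shape)
  for (b in seq_len(n_blobs)) {
    ctr <- runif(3, 0.25, 0.75) * (shape - 1) * spacing
    r <- runif(1, 1.2, 3.2) * mean(spacing)
    v <- v | ((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 <= r^2)
  }
  if (!any(v)) v[sample(length(v), 1)] <- TRUE
  binary_mask(v, grid = g)
}

random_volume <- function(shape = c(8, 8, 8), spacing = c(2.5, 2.5, 2.5),
                          lo = -1000, hi = 1000) {
  scalar_volume(array(runif(prod(shape), lo, hi), shape), spacing = spacing)
}

# smooth random velocity field: sum of a few Gaussian bumps per component,
# peak magnitude scaled to max_mm
random_smooth_velocity <- function(grid, max_mm = 10, n_bumps = 3) {
  co <- grid_coordinates(grid)
  L <- (grid$shape - 1) * grid$spacing
  vec <- array(0, c(grid$shape, 3))
  for (c in 1:3) {
    f <- array(0, grid$shape)
    for (b in seq_len(n_bumps)) {
      ctr <- grid$origin + runif(3, 0.2, 0.8) * L
      sig <- runif(3, 0.15, 0.3) * L
      amp <- runif(1, -1, 1)
      f <- f + amp * exp(-(((co$x - ctr[1]) / sig[1])^2 +
                          ((co$y - ctr[2]) / sig[2])^2 +
                          ((co$z - ctr[3]) / sig[3])^2) / 2)
    }
    vec[, , , c] <- f
  }
  m <- max(abs(vec))
  if (m > 0) vec <- vec * (max_mm / m)
  velocity_field(vec, grid = grid)
}

# dilate a logical array by a euclidean ball of the given voxel radius
cpp_dilate_wrap <- function(vals, dims, r) {
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  array(dvfsynth:::cpp_dilate(as.logical(vals), dims, off), dims)
}
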