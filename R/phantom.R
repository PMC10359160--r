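# smoothstep on [0, 1]
sstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# smooth 0/1 transition of an (approximate) signed distance d over width w mm
edge_frac <- function(d, w) {
  sstep(d / w + 0.5)
}

#' Specification of one synthetic thoracic phantom
#'
#' Describes the geometry of a paired diagnostic/planning phantom: an
#' elliptical body with a spine cylinder, two lungs bounded below by a
#' diaphragm dome, a spherical tumor (GTV), and a couch. The diagnostic state
#' has a curved couch (by default) and the exhale diaphragm position; the
#' planning state has a flat couch, the diaphragm dome displaced by
#' `diaphragm_shift` mm (breath-hold inflation, dome moved inferiorly so the
#' lungs enlarge), and the body contour scaled radially by `body_scale`.
#' Geometry defaults scale with the grid extent; the tumor radius is absolute
#' (default 9.05 mm, about 3.1 cc).
#'
#' @param shape,spacing,origin grid geometry (see [volume_grid()]).
#' @param body_radii axial ellipse semi-axes (mm), `c(rx, ry)`.
#' @param body_center ellipse center (mm), `c(x, y)`.
#' @param lung_params list of two lists, each `list(center = c(x,y,z), radii
#'   = c(rx,ry,rz))` in mm.
#' @param tumor `list(center = c(x,y,z), radius)` in mm.
#' @param spine `list(center = c(x,y), radius)` in mm.
#' @param diaphragm_z dome apex z (mm) in the diagnostic state.
#' @param diaphragm_droop dome droop coefficient (mm) away from the apex.
#' @param diaphragm_shift dome displacement magnitude between states (mm,
#'   >= 0; default 15).
#' @param body_scale fractional radial body-contour change (default 0.03).
#' @param couch_style diagnostic couch style (`"curved"` default); the
#'   planning couch is always flat.
#' @param noise_sd Gaussian intensity noise (HU, default 20).
#' @param edge_mm width of tissue transitions (mm); smooth interfaces emulate
#'   partial-volume blur and keep the analytic ground truth consistent with
#'   interpolated warps (default 6).
#' @param seed integer RNG seed; identical seeds give bit-identical cases.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = c(2.5, 2.5, 2.5),
                         origin = c(0, 0, 0),
                         body_radii = NULL, body_center = NULL,
                         lung_params = NULL, tumor = NULL, spine = NULL,
                         diaphragm_z = NULL, diaphragm_droop = NULL,
                         diaphragm_shift = 15, body_scale = 0.03,
                         couch_style = c("curved", "flat"),
                         noise_sd = 20, edge_mm = 6, seed = 1L) {
  couch_style <- match.arg(couch_style)
  grid <- volume_grid(shape, spacing, origin)
  L <- (grid$shape - 1) * grid$spacing
  ctr <- grid$origin + L / 2
  if (is.null(body_radii)) body_radii <- c(0.40 * L[1], 0.30 * L[2])
  if (is.null(body_center)) body_center <- c(ctr[1], grid$origin[2] + 0.42 * L[2])
  if (is.null(spine))
    spine <- list(center = c(body_center[1], body_center[2] + 0.60 * body_radii[2]),
                  radius = max(5, 0.12 * body_radii[2]))
  if (is.null(lung_params)) {
    mk <- function(side) list(
      center = c(body_center[1] + side * 0.45 * body_radii[1],
                 body_center[2] - 0.15 * body_radii[2],
                 grid$origin[3] + 0.55 * L[3]),
      radii = c(0.32 * body_radii[1], 0.55 * body_radii[2], 0.35 * L[3]))
    lung_params <- list(left = mk(-1), right = mk(1))
  }
  if (is.null(tumor))
    tumor <- list(center = c(body_center[1] + 0.45 * body_radii[1],
                             body_center[2] - 0.15 * body_radii[2],
                             grid$origin[3] + 0.65 * L[3]),
                  radius = 9.05)
  if (is.null(diaphragm_z)) diaphragm_z <- grid$origin[3] + 0.40 * L[3]
  if (is.null(diaphragm_droop)) diaphragm_droop <- 0.15 * L[3]
  if (diaphragm_shift < 0) stop("diaphragm_shift must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(grid = grid, body_radii = body_radii, body_center = body_center,
                 lung_params = lung_params, tumor = tumor, spine = spine,
                 diaphragm_z = diaphragm_z, diaphragm_droop = diaphragm_droop,
                 diaphragm_shift = diaphragm_shift, body_scale = body_scale,
                 couch_style = couch_style, noise_sd = noise_sd,
                 edge_mm = edge_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# couch model matching a phantom spec, for either state
phantom_couch <- function(spec, state = c("dct", "pct")) {
  state <- match.arg(state)
  style <- if (state == "dct") spec$couch_style else "flat"
  couch_model(style = style,
              top_y = spec$body_center[2] + spec$body_radii[2] + 4,
              thickness = 12,
              width = 1.7 * spec$body_radii[1],
              center_x = spec$body_center[1],
              curvature_radius = 3 * spec$body_radii[1],
              hu = 200)
}

# smooth tissue fractions of the (couchless) diagnostic-state anatomy at the
# physical coordinates x, y, z (arrays); returns clean HU plus the structure
# fractions used for masks
phantom_anatomy <- function(spec, x, y, z) {
  e <- spec$edge_mm
  bx <- spec$body_radii[1]; by <- spec$body_radii[2]
  cx <- spec$body_center[1]; cy <- spec$body_center[2]
  rho <- sqrt(((x - cx) / bx)^2 + ((y - cy) / by)^2)
  # the skin (air-body) interface is kept sharper than internal interfaces so
  # the thresholded body surface tracks the analytic ellipse closely
  f_body <- edge_frac((1 - rho) * min(bx, by), min(e, 4))
  # diaphragm dome surface: apex at diaphragm_z, drooping away from the body axis
  z_dome <- spec$diaphragm_z -
    spec$diaphragm_droop * (((x - cx) / bx)^2 + ((y - cy) / by)^2)
  f_above_dome <- edge_frac(z - z_dome, e)
  f_lung <- array(0, dim(x))
  for (lp in spec$lung_params) {
    q <- sqrt(((x - lp$center[1]) / lp$radii[1])^2 +
              ((y - lp$center[2]) / lp$radii[2])^2 +
              ((z - lp$center[3]) / lp$radii[3])^2)
    f_ell <- edge_frac((1 - q) * min(lp$radii), e)
    f_lung <- pmax(f_lung, f_ell)
  }
  f_lung <- f_lung * f_above_dome * f_body
  dt <- sqrt((x - spec$tumor$center[1])^2 + (y - spec$tumor$center[2])^2 +
             (z - spec$tumor$center[3])^2)
  # tumor boundaries are comparatively sharp on CT; cap the blur so the core
  # keeps its nominal intensity even for centimetre-scale lesions
  f_tumor <- edge_frac(spec$tumor$radius - dt, min(e, 4))
  ds <- sqrt((x - spec$spine$center[1])^2 + (y - spec$spine$center[2])^2)
  f_spine <- edge_frac(spec$spine$radius - ds, e) * f_body
  hu <- -1000 + 1040 * f_body
  hu <- hu + (-750 - hu) * f_lung
  hu <- hu + (60 - hu) * f_tumor
  hu <- hu + (700 - hu) * f_spine
  list(hu = hu, f_body = f_body, f_lung = f_lung, f_tumor = f_tumor)
}

# analytic ground-truth displacement (pull-back: planning-state positions map
# into the diagnostic state) evaluated at physical coordinates
phantom_displacement <- function(spec, x, y, z) {
  g <- spec$grid
  L <- (g$shape - 1) * g$spacing
  lo <- g$origin
  hi <- g$origin + L
  margin <- 0.18 * L
  W <- sstep((x - lo[1]) / margin[1]) * sstep((hi[1] - x) / margin[1]) *
       sstep((y - lo[2]) / margin[2]) * sstep((hi[2] - y) / margin[2]) *
       sstep((z - lo[3]) / margin[3]) * sstep((hi[3] - z) / margin[3])
  sp <- spec$spine
  rsp2 <- (x - sp$center[1])^2 + (y - sp$center[2])^2
  spine_win <- 1 - exp(-rsp2 / (2 * (2 * sp$radius)^2))
  bx <- spec$body_radii[1]; by <- spec$body_radii[2]
  cx <- spec$body_center[1]; cy <- spec$body_center[2]
  # diaphragm mode: z-directed Gaussian bump centered at the dome apex
  sig <- c(0.45 * bx, 0.45 * by, 0.20 * L[3])
  gbump <- exp(-(((x - cx) / sig[1])^2 + ((y - cy) / sig[2])^2 +
                 ((z - spec$diaphragm_z) / sig[3])^2) / 2)
  uz <- spec$diaphragm_shift * gbump * W * spine_win
  # body-contour mode: radial scaling about the spine axis
  h <- spec$body_scale * W * spine_win
  ux <- -h * (x - sp$center[1])
  uy <- -h * (y - sp$center[2])
  list(ux = ux, uy = uy, uz = uz)
}

render_state <- function(spec, deformed) {
  g <- spec$grid
  co <- grid_coordinates(g)
  if (deformed) {
    u <- phantom_displacement(spec, co$x, co$y, co$z)
    px <- co$x + u$ux; py <- co$y + u$uy; pz <- co$z + u$uz
  } else {
    px <- co$x; py <- co$y; pz <- co$z
  }
  an <- phantom_anatomy(spec, px, py, pz)
  couch <- phantom_couch(spec, if (deformed) "pct" else "dct")
  depth <- couch_depth(couch, co$x, co$y)
  inside_band <- pmin(edge_frac(depth, spec$edge_mm),
                      edge_frac(couch$thickness - depth, spec$edge_mm))
  width_win <- edge_frac(couch$width / 2 - abs(co$x - couch$center_x), spec$edge_mm)
  f_couch <- inside_band * width_win * (1 - an$f_body)
  hu <- an$hu + (couch$hu - an$hu) * f_couch
  list(hu = hu, fractions = an)
}

#' Generate one paired synthetic thoracic phantom
#'
#' Builds the diagnostic-state volume (curved couch, exhale diaphragm), the
#' planning-state volume (flat couch, diaphragm displaced, body contour
#' scaled), the analytic ground-truth displacement field linking them
#' (pull-back convention: warping the diagnostic volume with it reproduces the
#' planning anatomy), and body/lungs/gtv masks on both grids. Tissue values:
#' air -1000, lung about -750, soft tissue about 40, tumor about 60, spine
#' bone about 700, couch 200 HU, plus Gaussian noise. The couch is excluded
#' from the deformation.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: a list with `dct`, `pct`
#'   ([scalar_volume()]s), `true_dvf` ([displacement_field()]), `masks_dct`,
#'   `masks_pct` (named lists of [binary_mask()]s: body, lungs, gtv),
#'   noise-free `dct_clean`/`pct_clean`, and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  dct_state <- render_state(spec, deformed = FALSE)
  pct_state <- render_state(spec, deformed = TRUE)
  masks_from <- function(fr) {
    list(body = binary_mask(fr$f_body > 0.5, grid = g),
         lungs = binary_mask(fr$f_lung > 0.5, grid = g),
         gtv = binary_mask(fr$f_tumor > 0.5, grid = g))
  }
  masks_dct <- masks_from(dct_state$fractions)
  masks_pct <- masks_from(pct_state$fractions)
  for (nm in names(masks_dct)) {
    if (!any(masks_dct[[nm]]$values) || !any(masks_pct[[nm]]$values))
      stop(sprintf("phantom geometry produced an empty '%s' mask", nm),
           call. = FALSE)
  }
  if (any(masks_dct$lungs$values & !masks_dct$body$values))
    stop("phantom geometry invalid: lungs extend outside the body", call. = FALSE)
  if (any(masks_dct$gtv$values & !masks_dct$lungs$values))
    stop("phantom geometry invalid: tumor extends outside the lungs", call. = FALSE)
  co <- grid_coordinates(g)
  u <- phantom_displacement(spec, co$x, co$y, co$z)
  true_dvf <- displacement_field(array(c(u$ux, u$uy, u$uz), c(g$shape, 3L)),
                                 grid = g)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  n <- prod(g$shape)
  noisy <- function(hu) {
    if (spec$noise_sd > 0) hu <- hu + array(rnorm(n, 0, spec$noise_sd), g$shape)
    scalar_volume(hu, grid = g)
  }
  dct <- noisy(dct_state$hu)
  pct <- noisy(pct_state$hu)
  structure(list(dct = dct, pct = pct, true_dvf = true_dvf,
                 masks_dct = masks_dct, masks_pct = masks_pct,
                 dct_clean = scalar_volume(dct_state$hu, grid = g),
                 pct_clean = scalar_volume(pct_state$hu, grid = g),
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, diaphragm shift %.1f mm, seed %d\n",
              paste(x$spec$grid$shape, collapse = " x "),
              x$spec$diaphragm_shift, x$spec$seed))
  invisible(x)
}

#' Default anatomical jitter ranges for [make_dataset()]
#'
#' Uniform ranges emulating inter-patient variation: diaphragm displacement
#' 10-20 mm, body-contour change 1-5%, body size within 8%, tumor radius
#' within 10% (GTV volumes around 3.1 cc; `gtv_cc_range` documents the
#' expected cohort range), tumor position within 3 mm, dome apex within 3% of
#' the scan length.
#'
#' @return A named list of `c(lo, hi)` ranges.
#' @export
phantom_jitter <- function() {
  list(diaphragm_shift = c(10, 20),
       body_scale = c(0.01, 0.05),
       body_radii_scale = c(0.92, 1.08),
       tumor_radius_scale = c(0.90, 1.10),
       tumor_center_mm = c(-3, 3),
       diaphragm_z_frac = c(-0.03, 0.03),
       gtv_cc_range = c(2.2, 4.2))
}

runif_range <- function(r) {
  if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
    stop("jitter ranges must be finite pairs with lo <= hi", call. = FALSE)
  runif(1, r[1], r[2])
}

#' Generate a jittered phantom dataset
#'
#' Draws `n_cases` phantoms with per-case seeds `base_seed + index` (0-based
#' index) and anatomical parameters jittered uniformly within the ranges of
#' the descriptor; reproducible for a fixed `base_seed`.
#'
#' @param n_cases number of cases (>= 1).
#' @param base_seed integer.
#' @param jitter ranges as from [phantom_jitter()].
#' @param shape,spacing grid geometry passed to [phantom_spec()].
#' @return A list of `phantom_case`s.
#' @export
make_dataset <- function(n_cases, base_seed = 0L, jitter = phantom_jitter(),
                         shape = c(96, 96, 96), spacing = c(2.5, 2.5, 2.5)) {
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L)
    stop("n_cases must be >= 1", call. = FALSE)
  lapply(seq_len(n_cases), function(i) {
    seed_i <- as.integer(base_seed) + i - 1L
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed_i + 90001L)
    base <- phantom_spec(shape = shape, spacing = spacing, seed = seed_i)
    L <- (base$grid$shape - 1) * base$grid$spacing
    spec <- phantom_spec(
      shape = shape, spacing = spacing,
      body_radii = base$body_radii * runif_range(jitter$body_radii_scale),
      diaphragm_shift = runif_range(jitter$diaphragm_shift),
      body_scale = runif_range(jitter$body_scale),
      diaphragm_z = base$diaphragm_z + L[3] * runif_range(jitter$diaphragm_z_frac),
      noise_sd = base$noise_sd,
      seed = seed_i)
    spec$tumor$radius <- spec$tumor$radius * runif_range(jitter$tumor_radius_scale)
    spec$tumor$center <- spec$tumor$center +
      c(runif_range(jitter$tumor_center_mm),
        runif_range(jitter$tumor_center_mm),
        runif_range(jitter$tumor_center_mm))
    make_phantom(spec)
  })
}

#' Voxel volume of a mask in cubic centimetres
#'
#' @param mask a [binary_mask()].
#' @return Volume in cc.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$grid$spacing) / 1000
}
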