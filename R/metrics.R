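#' Root averaged squared sum of differences (RASSD)
#'
#' Root-mean-square intensity discrepancy (HU) between two aligned volumes,
#' optionally restricted to a region.
#'
#' @param a,b [scalar_volume()]s on the same grid.
#' @param region optional [binary_mask()].
#' @return Nonnegative scalar (HU).
#' @export
rassd <- function(a, b, region = NULL) {
  stopifnot(inherits(a, "scalar_volume"), inherits(b, "scalar_volume"))
  stop_if_grid_mismatch(a$grid, b$grid, "volumes")
  d <- region_values((a$values - b$values)^2, region, a$grid)
  if (length(d) == 0L) stop("empty comparison region", call. = FALSE)
  sqrt(mean(d))
}

#' Dice similarity coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)`. Two empty masks agree perfectly (1); one
#' empty mask against a nonempty one scores 0.
#'
#' @param x,y [binary_mask()]s on the same grid.
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(x, y) {
  stopifnot(inherits(x, "binary_mask"), inherits(y, "binary_mask"))
  stop_if_grid_mismatch(x$grid, y$grid, "masks")
  nx <- sum(x$values)
  ny <- sum(y$values)
  if (nx + ny == 0L) return(1)
  2 * sum(x$values & y$values) / (nx + ny)
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one background 6-neighbor; voxels beyond
#' the array border count as background, so foreground touching the volume
#' boundary is surface.
#'
#' @param mask a [binary_mask()].
#' @return Integer matrix of 1-based voxel indices (one row per surface voxel).
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- mask$values
  d <- dim(v)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

#' Hausdorff distance between two masks
#'
#' Exact symmetric max-min Euclidean distance (mm, spacing aware) between the
#' surface voxel sets of the two masks.
#'
#' @param x,y nonempty [binary_mask()]s on the same grid.
#' @return Nonnegative scalar (mm).
#' @export
hausdorff <- function(x, y) {
  stopifnot(inherits(x, "binary_mask"), inherits(y, "binary_mask"))
  stop_if_grid_mismatch(x$grid, y$grid, "masks")
  if (!any(x$values) || !any(y$values))
    stop("hausdorff distance requires nonempty masks", call. = FALSE)
  sa <- surface_voxels(x)
  sb <- surface_voxels(y)
  g <- x$grid
  mm <- function(idx) sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  pa <- mm(sa)
  pb <- mm(sb)
  cpp_hausdorff(pa[, 1], pa[, 2], pa[, 3], pb[, 1], pb[, 2], pb[, 3])
}

crop_z <- function(obj, zr) {
  vals <- obj$values[, , zr[1]:zr[2], drop = FALSE]
  g <- obj$grid
  ng <- volume_grid(dim(vals), g$spacing,
                    g$origin + c(0, 0, (zr[1] - 1) * g$spacing[3]))
  if (inherits(obj, "binary_mask")) binary_mask(vals, grid = ng)
  else scalar_volume(vals, grid = ng)
}

#' Evaluate one synthesized case against its target
#'
#' Computes RASSD, Dice, and Hausdorff distance per structure, plus the
#' folding fraction of the deformation. Because the two scans may cover
#' different superior-inferior extents, the body comparison is restricted to
#' the overlapping z-slice interval of the two body masks; RASSD for the body
#' uses the whole overlapping volume, other structures use their union mask.
#'
#' @param sct synthesized [scalar_volume()].
#' @param pct target [scalar_volume()] on the same grid.
#' @param masks_s,masks_p named lists of [binary_mask()]s with matching names
#'   (e.g. `body`, `lungs`, `gtv`).
#' @param dvf the [displacement_field()] that produced `sct`.
#' @return An object of class `case_report`: a list with `structures` (a
#'   data.frame of per-structure rassd/dsc/hd), `folding_fraction`, and
#'   `z_range_used`.
#' @export
evaluate_case <- function(sct, pct, masks_s, masks_p, dvf) {
  stopifnot(inherits(sct, "scalar_volume"), inherits(pct, "scalar_volume"))
  stop_if_grid_mismatch(sct$grid, pct$grid, "sct and pct")
  if (!setequal(names(masks_s), names(masks_p)) || is.null(names(masks_s)))
    stop("mask sets must have matching structure names", call. = FALSE)
  structs <- names(masks_s)
  zr <- if ("body" %in% structs)
    overlapping_z_range(masks_s[["body"]], masks_p[["body"]])
  else
    c(1L, sct$grid$shape[3])
  rows <- lapply(structs, function(s) {
    ms <- masks_s[[s]]
    mp <- masks_p[[s]]
    stop_if_grid_mismatch(ms$grid, sct$grid, sprintf("mask '%s' and sct", s))
    stop_if_grid_mismatch(mp$grid, pct$grid, sprintf("mask '%s' and pct", s))
    if (s == "body" && length(zr) == 2L) {
      a <- crop_z(sct, zr); b <- crop_z(pct, zr)
      ms <- crop_z(ms, zr); mp <- crop_z(mp, zr)
      r <- rassd(a, b)                 # whole overlapping volume
    } else {
      un <- binary_mask(ms$values | mp$values, grid = ms$grid)
      r <- if (any(un$values)) rassd(sct, pct, region = un) else NA_real_
    }
    data.frame(structure = s,
               rassd = r,
               dsc = dsc(ms, mp),
               hd = if (any(ms$values) && any(mp$values)) hausdorff(ms, mp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(structures = do.call(rbind, rows),
                 folding_fraction = folding_fraction(dvf),
                 z_range_used = zr),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>\n")
  print(x$structures, row.names = FALSE)
  cat(sprintf("folding fraction: %g; z range: %s\n", x$folding_fraction,
              if (length(x$z_range_used)) paste(x$z_range_used, collapse = "-")
              else "empty"))
  invisible(x)
}

#' Aggregate case reports into a cohort table
#'
#' @param reports nonempty list of `case_report`s.
#' @return A data.frame with one row per structure and metric, holding mean,
#'   median, min and max across cases (folding fraction aggregated as its own
#'   row).
#' @export
cohort_summary <- function(reports) {
  if (!is.list(reports) || length(reports) == 0L ||
      !all(vapply(reports, inherits, logical(1), "case_report")))
    stop("reports must be a nonempty list of case_report objects", call. = FALSE)
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    d <- reports[[i]]$structures
    d$case <- i
    d
  }))
  long <- do.call(rbind, lapply(c("rassd", "dsc", "hd"), function(m) {
    data.frame(structure = tab$structure, metric = m, value = tab[[m]],
               stringsAsFactors = FALSE)
  }))
  fold <- data.frame(structure = "(field)", metric = "folding_fraction",
                     value = vapply(reports, `[[`, numeric(1), "folding_fraction"),
                     stringsAsFactors = FALSE)
  long <- rbind(long, fold)
  out <- stats::aggregate(value ~ structure + metric, long,
                          function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  names(out)[3] <- "mean"
  out$median <- stats::aggregate(value ~ structure + metric, long,
                                 function(v) median(v, na.rm = TRUE),
                                 na.action = stats::na.pass)$value
  out$min <- stats::aggregate(value ~ structure + metric, long,
                              function(v) suppressWarnings(min(v, na.rm = TRUE)),
                              na.action = stats::na.pass)$value
  out$max <- stats::aggregate(value ~ structure + metric, long,
                              function(v) suppressWarnings(max(v, na.rm = TRUE)),
                              na.action = stats::na.pass)$value
  out[order(out$structure, out$metric), , drop = FALSE]
}
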