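test_that("rassd follows its closed forms", {
  a <- scalar_volume(array(0, c(2, 2, 2)))
  d <- scalar_volume(array(c(1, 1, 1, 1, 3, 3, 3, 3), c(2, 2, 2)))
  expect_equal(rassd(a, a), 0)
  expect_equal(rassd(a, d), sqrt(5))                 # hand-computed RMS
  off <- scalar_volume(a$values + 12, grid = a$grid)
  expect_equal(rassd(a, off), 12)
  empty <- binary_mask(array(FALSE, c(2, 2, 2)), grid = a$grid)
  expect_error(rassd(a, d, region = empty), "empty")
})

test_that("dice follows its counting definition including empty-mask edge cases", {
  g <- volume_grid(c(8, 8, 8))
  mk <- function(idx) {
    v <- array(FALSE, g$shape)
    v[idx] <- TRUE
    binary_mask(v, grid = g)
  }
  x <- mk(1:100)
  y <- mk(61:120)
  expect_equal(dsc(x, y), 2 * 40 / 160)
  expect_equal(dsc(x, x), 1)
  expect_equal(dsc(mk(1:10), mk(101:110)), 0)
  e <- mk(integer(0))
  expect_equal(dsc(e, e), 1)
  expect_equal(dsc(e, x), 0)
})

test_that("hausdorff distance of simple configurations is exact", {
  g <- volume_grid(c(10, 10, 10), spacing = c(2.5, 2.5, 2.5))
  mk <- function(i, j, k) {
    v <- array(FALSE, g$shape)
    v[i, j, k] <- TRUE
    binary_mask(v, grid = g)
  }
  a <- mk(2, 2, 2)
  b <- mk(6, 2, 2)   # 4 voxels = 10 mm apart
  expect_equal(hausdorff(a, b), 10)
  expect_equal(hausdorff(a, a), 0)
  expect_error(hausdorff(a, binary_mask(array(FALSE, g$shape), grid = g)),
               "nonempty")
})

test_that("rassd, dice and hausdorff match brute-force oracles on random cases", {
  set.seed(31)
  for (r in 1:15) {
    a <- random_volume(c(6, 6, 6))
    b <- random_volume(c(6, 6, 6))
    expect_equal(rassd(a, b), oracle_rassd(a, b), tolerance = 1e-10)
    x <- random_small_mask()
    y <- random_small_mask()
    expect_identical(dsc(x, y), oracle_dsc(x, y))
    expect_identical(hausdorff(x, y), oracle_hausdorff(x, y))
    expect_identical(hausdorff(x, y), hausdorff(y, x))   # symmetry
  }
})

test_that("hausdorff satisfies the triangle-type bound on mask triples", {
  set.seed(32)
  for (r in 1:8) {
    a <- random_small_mask()
    b <- random_small_mask()
    c <- random_small_mask()
    expect_lte(hausdorff(a, c), hausdorff(a, b) + hausdorff(b, c) + 1e-9)
  }
})

test_that("dice is monotone under erosion of a nested mask", {
  case <- small_phantom(seed = 1)
  lungs <- case$masks_dct$lungs
  v <- lungs$values
  eroded1 <- binary_mask(!cpp_dilate_wrap(!v, dim(v), 1), grid = lungs$grid)
  eroded2 <- binary_mask(!cpp_dilate_wrap(!v, dim(v), 2), grid = lungs$grid)
  d0 <- dsc(lungs, lungs)
  d1 <- dsc(eroded1, lungs)
  d2 <- dsc(eroded2, lungs)
  expect_true(d0 >= d1 && d1 >= d2)
  expect_lt(d2, 1)
})

test_that("self-evaluation of a case is perfect", {
  case <- small_phantom(seed = 1)
  rep <- evaluate_case(case$pct, case$pct, case$masks_pct, case$masks_pct,
                       zero_displacement(case$pct$grid))
  expect_true(all(rep$structures$rassd == 0))
  expect_true(all(rep$structures$dsc == 1))
  expect_true(all(rep$structures$hd == 0))
  expect_equal(rep$folding_fraction, 0)
})

test_that("ground-truth warping scores high overlap against the planning masks", {
  case <- small_phantom(seed = 1)
  sct <- warp(remove_couch(case$dct, case$masks_dct$body), case$true_dvf)
  warped_masks <- lapply(case$masks_dct, warp_mask, dvf = case$true_dvf)
  rep <- evaluate_case(sct, remove_couch(case$pct, case$masks_pct$body),
                       warped_masks, case$masks_pct, case$true_dvf)
  lung <- rep$structures[rep$structures$structure == "lungs", ]
  expect_gt(lung$dsc, 0.95)
  expect_equal(rep$folding_fraction, 0)
  expect_gt(rep$structures$dsc[rep$structures$structure == "body"], 0.97)
})

test_that("evaluation restricts the body comparison to overlapping slices", {
  case <- small_phantom(seed = 1)
  masks_s <- case$masks_dct
  masks_p <- case$masks_pct
  # blank the top 10 slices of one body mask to emulate a shorter scan
  v <- masks_s$body$values
  v[, , 39:48] <- FALSE
  masks_s$body <- binary_mask(v, grid = masks_s$body$grid)
  rep <- evaluate_case(case$dct, case$pct, masks_s, masks_p,
                       zero_displacement(case$dct$grid))
  za <- range(which(apply(v, 3, any)))
  zb <- range(which(apply(masks_p$body$values, 3, any)))
  expect_equal(rep$z_range_used, c(max(za[1], zb[1]), min(za[2], zb[2])))
  expect_error(evaluate_case(case$dct, case$pct, masks_s["body"],
                             masks_p["lungs"],
                             zero_displacement(case$dct$grid)),
               "matching structure names")
})

test_that("cohort summaries aggregate per structure and metric", {
  case <- small_phantom(seed = 1)
  z <- zero_displacement(case$pct$grid)
  r1 <- evaluate_case(case$pct, case$pct, case$masks_pct, case$masks_pct, z)
  s1 <- cohort_summary(list(r1))
  expect_setequal(unique(s1$metric), c("rassd", "dsc", "hd", "folding_fraction"))
  got <- s1$mean[s1$structure == "lungs" & s1$metric == "dsc"]
  expect_equal(got, 1)
  # two synthetic reports with dsc 0.8 and 1.0 average to 0.9
  r2 <- r1
  r2$structures$dsc <- 0.8
  r1b <- r1
  r1b$structures$dsc <- 1.0
  s2 <- cohort_summary(list(r1b, r2))
  expect_equal(s2$mean[s2$metric == "dsc"], rep(0.9, 3))
  expect_equal(s2$min[s2$metric == "dsc"], rep(0.8, 3))
  expect_error(cohort_summary(list()), "nonempty")
})
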