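# Segmentation metrics, paired statistics, DVH and plan metrics.

rand_mask <- function(dm, p = 0.2) {
  m <- array(runif(prod(dm)) < p, dim = dm)
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}

test_that("dice: identity, disjoint, arithmetic, symmetry, range", {
  dm <- c(8, 8, 8)
  a <- array(FALSE, dim = dm); a[1:5, 1:5, 1:4] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, dim = dm); b[6:8, 6:8, 5:8] <- TRUE
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 100, overlap 80
  a2 <- array(FALSE, dim = c(10, 10, 2)); a2[1:10, 1:10, 1] <- TRUE
  b2 <- array(FALSE, dim = c(10, 10, 2))
  b2[1:8, 1:10, 1] <- TRUE; b2[1:10, 1:2, 2] <- TRUE
  expect_equal(sum(a2), 100); expect_equal(sum(b2), 100)
  expect_equal(dice(a2, b2), 0.8)
  expect_equal(dice(array(FALSE, dim = dm), array(FALSE, dim = dm)), 1)
  set.seed(31)
  for (r in 1:10) {
    x <- rand_mask(dm); y <- rand_mask(dm)
    d <- dice(x, y)
    expect_equal(d, dice(y, x))
    expect_true(d >= 0 && d <= 1)
  }
  expect_error(dice(a, array(FALSE, dim = c(4, 4, 4))), "grid")
})

test_that("surface extraction: singleton, solid cube shell, hollow shell", {
  dm <- c(9, 9, 9)
  one <- array(FALSE, dim = dm); one[4, 5, 6] <- TRUE
  s <- surface_voxels(mask3d(one, c(2, 2, 2)))
  expect_equal(nrow(s), 1L)
  expect_equal(as.numeric(s), c(3, 4, 5) * 2)

  cube <- array(FALSE, dim = dm); cube[3:7, 3:7, 3:7] <- TRUE
  expect_equal(nrow(surface_voxels(mask3d(cube, c(1, 1, 1)))), 98L) # 5^3 - 3^3

  shell <- cube; shell[4:6, 4:6, 4:6] <- FALSE
  expect_equal(nrow(surface_voxels(mask3d(shell, c(1, 1, 1)))), sum(shell))
  expect_error(surface_voxels(mask3d(array(FALSE, dim = dm), c(1, 1, 1))),
               "empty")
})

test_that("hausdorff: identity, direct distances, brute-force oracle", {
  dm <- c(8, 8, 8)
  a <- array(FALSE, dim = dm); a[2:5, 2:5, 2:5] <- TRUE
  expect_equal(hausdorff(a, a, spacing = c(1, 1, 1)), 0)

  # two single voxels 3 apart along a 4 mm axis
  x <- array(FALSE, dim = dm); x[2, 4, 4] <- TRUE
  y <- array(FALSE, dim = dm); y[5, 4, 4] <- TRUE
  expect_equal(hausdorff(mask3d(x, c(4, 1, 1)), mask3d(y, c(4, 1, 1))), 12)

  set.seed(32)
  for (r in 1:25) {
    sp <- sample(c(1, 1.17, 2, 4), 3, replace = TRUE)
    x <- mask3d(rand_mask(c(6, 7, 5), 0.25), sp)
    y <- mask3d(rand_mask(c(6, 7, 5), 0.25), sp)
    expect_equal(hausdorff(x, y),
                 oracle_hausdorff(surface_voxels(x), surface_voxels(y)))
    expect_equal(hausdorff(x, y), hausdorff(y, x))
  }
  expect_error(hausdorff(a, array(FALSE, dim = dm), c(1, 1, 1)), "non-empty")
})

test_that("paired t-test matches the closed form and the printed tables", {
  tab <- example_table("ptv_dosimetry")
  dm <- tab[tab$metric == "dmean", ]
  r <- paired_t_test(dm$plan_a, dm$plan_b)
  expect_equal(round(r$p, 4), 0.0015)
  d98 <- tab[tab$metric == "d98", ]
  expect_equal(round(paired_t_test(d98$plan_a, d98$plan_b)$p, 2), 0.90)

  # n = 2 closed form: d = (1, 3) gives t = 2; p = 2 * P(T_1 < -2)
  r2 <- paired_t_test(c(0, 0), c(1, 3))
  expect_equal(r2$t, 2)
  expect_equal(r2$p, 0.2951672, tolerance = 1e-6)
  expect_equal(r2$p, oracle_pt2(2, 1), tolerance = 1e-6)

  # a single perturbed pair sets the sign of t
  x <- 1:6
  up <- x; up[3] <- up[3] + 1
  expect_gt(paired_t_test(x, up)$t, 0)
  expect_lt(paired_t_test(up, x)$t, 0)

  expect_error(paired_t_test(1:4, 1:4 + 2), "zero-variance")
  expect_error(paired_t_test(1:3, 1:4), "equal length")

  # independently coded t-distribution CDF, all df <= 30
  for (df in c(1:6, 10, 20, 30))
    for (t in c(0.3, 1.2, 2.7, 5))
      expect_equal(2 * stats::pt(-t, df), oracle_pt2(t, df), tolerance = 1e-6)
  # and the implementation agrees with stats::t.test
  set.seed(33)
  x <- rnorm(9); y <- rnorm(9, 0.4)
  r3 <- paired_t_test(x, y)
  tt <- stats::t.test(y, x, paired = TRUE)
  expect_equal(r3$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r3$p, tt$p.value, tolerance = 1e-12)
})

test_that("cumulative DVH: steps, ramps, refinement, monotonicity", {
  dm <- c(10, 10, 10)
  st <- array(TRUE, dim = dm)
  u <- array(60, dim = dm)
  dvh <- compute_dvh(u, st, 0.1)
  expect_equal(dvh$volume_fraction[dvh$dose_gy <= 60],
               rep(1, sum(dvh$dose_gy <= 60)))
  expect_equal(dvh$volume_fraction[dvh$dose_gy > 60],
               rep(0, sum(dvh$dose_gy > 60)))

  ramp <- array(seq(0, 100, length.out = prod(dm)), dim = dm)
  dvh2 <- compute_dvh(ramp, st, 0.5)
  expected <- pmax(0, 1 - dvh2$dose_gy / 100)
  expect_lt(max(abs(dvh2$volume_fraction - expected)), 0.5 / 100 + 1e-6)
  expect_true(all(diff(dvh2$volume_fraction) <= 0))
  expect_equal(dvh2$volume_fraction[1], 1)

  # halving the bin width agrees at shared bin edges
  dvh3 <- compute_dvh(ramp, st, 0.25)
  shared <- match(round(dvh2$dose_gy, 6), round(dvh3$dose_gy, 6))
  ok <- !is.na(shared)
  expect_gt(sum(ok), 100)
  expect_equal(dvh3$volume_fraction[shared[ok]], dvh2$volume_fraction[ok])

  expect_error(compute_dvh(u, array(FALSE, dim = dm)), "empty")
})

test_that("dose metrics and heterogeneity indexes", {
  dm <- c(10, 10, 10)
  st <- array(TRUE, dim = dm)
  u <- array(60, dim = dm)
  pm <- dose_metrics(u, st, dp = 60, ri = 60, vx_thresholds = 60)
  expect_equal(pm$d2, 60); expect_equal(pm$d98, 60); expect_equal(pm$dmean, 60)
  expect_equal(pm$hi_rtog, 1)
  expect_identical(pm$hi_d2d98, 0)
  expect_equal(unname(pm$vx["V60"]), 100)
  expect_true(pm$compliant)

  # direct formula: d2 = 67.50, d98 = 60.00, dp = 60
  expect_equal((67.50 - 60.00) / 60 * 100, 12.5)

  ramp <- array(seq(0, 100, length.out = prod(dm)), dim = dm)
  pr <- dose_metrics(ramp, st, dp = 60)
  expect_equal(pr$d2, 98, tolerance = 0.2)
  expect_equal(pr$d98, 2, tolerance = 0.2)
  d50 <- mtvseg:::dose_at_volume(sort(ramp[st], decreasing = TRUE), 50)
  expect_true(pr$d2 >= d50 && d50 >= pr$d98)
  expect_false(dose_metrics(ramp, st, dp = 60, ri = 40)$compliant) # 100/40 > 2

  expect_error(dose_metrics(u, st, dp = 0), "dp")
  expect_error(dose_metrics(u, st, dp = 60, ri = -1), "ri")
})

test_that("segmentation evaluation couples DSC and HD consistently", {
  a <- array(FALSE, dim = c(8, 8, 8)); a[2:6, 2:6, 2:6] <- TRUE
  r <- evaluate_segmentation(mask3d(a, c(1, 1, 1)), mask3d(a, c(1, 1, 1)))
  expect_equal(r$dsc, 1)
  expect_equal(r$hd_mm, 0)
})
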