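# Metabolic sub-volume partitioning, the minimum-size merge rule,
# measurement reporting, margin expansion.

make_partition_fixture <- function() {
  # 20x20x6 tumor slab with planted class values
  dm <- c(24, 24, 8)
  arr <- array(0.1, dim = dm)
  tumor <- array(FALSE, dim = dm)
  tumor[3:22, 3:22, 2:7] <- TRUE
  arr[tumor] <- 10                        # high by default
  arr[3:12, 3:22, 2:7] <- 4               # mod
  arr[3:12, 3:12, 2:7] <- 2               # low
  arr[5, 5, 4] <- 10                      # ensure SUVmax inside low block? no:
  arr[22, 22, 7] <- 10                    # keep the global max in the high block
  arr[5, 5, 4] <- 2
  v <- suv_volume(arr, c(2, 2, 2))
  list(vol = v, tumor = mask3d(tumor, c(2, 2, 2)))
}

test_that("partitioning follows the half-open fractional-SUV brackets", {
  fx <- make_partition_fixture()
  part <- partition_subvolumes(fx$vol, fx$tumor)
  cls <- part$class_map$labels
  fg <- mtvseg:::mask_fg(fx$tumor)
  expect_equal(sum(cls != 0L), sum(fg))             # nonzero exactly on tumor
  expect_equal(part$suv_max_ref, 10)
  expect_true(all(cls[fx$vol$data == 2 & fg] == 1L))
  expect_true(all(cls[fx$vol$data == 4 & fg] == 2L))
  expect_true(all(cls[fx$vol$data == 10 & fg] == 3L))

  # exact boundary: f == 25% SUVmax is low; epsilon above is mod
  dm <- c(6, 6, 6)
  arr <- array(10, dim = dm)
  arr[2, 2, 2] <- 2.5
  arr[3, 3, 3] <- 2.5 + 1e-9
  p <- partition_subvolumes(suv_volume(arr, c(1, 1, 1)),
                            mask3d(array(TRUE, dim = dm), c(1, 1, 1)))
  expect_equal(p$class_map$labels[2, 2, 2], 1L)
  expect_equal(p$class_map$labels[3, 3, 3], 2L)

  # the SUVmax voxel is always class high
  wh <- which(fx$vol$data == 10 & fg, arr.ind = TRUE)[1, ]
  expect_equal(cls[wh[1], wh[2], wh[3]], 3L)
})

test_that("partition classifies planted voxel counts exactly", {
  dm <- c(32, 30, 10)
  arr <- array(0, dim = dm)
  tumor <- array(FALSE, dim = dm)
  # planted blocks: 1000 low, 800 mod, 600 high voxels
  tumor[1:10, 1:10, 1:10] <- TRUE; arr[1:10, 1:10, 1:10] <- 2    # 1000 low
  tumor[12:21, 1:10, 1:8] <- TRUE; arr[12:21, 1:10, 1:8] <- 4    # 800 mod
  tumor[23:32, 1:10, 1:6] <- TRUE; arr[23:32, 1:10, 1:6] <- 10   # 600 high
  p <- partition_subvolumes(suv_volume(arr, c(1, 1, 1)),
                            mask3d(tumor, c(1, 1, 1)))
  expect_equal(as.integer(table(factor(p$class_map$labels[tumor],
                                       levels = 1:3))),
               c(1000L, 800L, 600L))
})

test_that("small components merge into their nearest sub-volume", {
  fx <- make_partition_fixture()
  part <- partition_subvolumes(fx$vol, fx$tumor)
  n_before <- sum(part$class_map$labels != 0L)
  merged <- merge_small_components(part, 25L)
  # all planted components are large: identity
  expect_identical(merged$class_map$labels, part$class_map$labels)

  # a 10-voxel moderate island inside a large high region is relabelled high
  dm <- c(16, 16, 8)
  arr <- array(10, dim = dm)
  arr[7:11, 8, 4:5] <- 4 # 10 voxels
  tumor <- mask3d(array(TRUE, dim = dm), c(1, 1, 1))
  p <- partition_subvolumes(suv_volume(arr, c(1, 1, 1)), tumor)
  m <- merge_small_components(p, 25L)
  expect_true(all(m$class_map$labels == 3L))
  expect_equal(m$merges$from_class, "mod")
  expect_equal(m$merges$to_class, "high")
  # conservation through merging
  expect_equal(sum(m$class_map$labels != 0L), prod(dm))

  # 24 voxels merge, 25 voxels survive (the 5x5x1 grid-cell limit)
  for (nv in c(24L, 25L)) {
    arr2 <- array(10, dim = dm)
    arr2[5:9, 5:9, 4] <- 4
    if (nv == 24L) arr2[5, 5, 4] <- 10
    p2 <- partition_subvolumes(suv_volume(arr2, c(1, 1, 1)), tumor)
    m2 <- merge_small_components(p2, 25L)
    if (nv == 24L) expect_true(all(m2$class_map$labels == 3L))
    else expect_equal(sum(m2$class_map$labels == 2L), 25L)
  }
  expect_equal(n_before, sum(merged$class_map$labels != 0L))
})

test_that("measurement reproduces planning-report arithmetic", {
  tab <- example_table("subvolume_measurements")
  for (i in seq_len(nrow(tab))) {
    rep <- measure_subvolumes(c(low = tab$ptv_low_ml[i],
                                mod = tab$ptv_mod_ml[i],
                                high = tab$ptv_high_ml[i]),
                              total_ml = tab$ptv_ml[i])
    # agreement to one unit in the last printed digit (the ml inputs are
    # themselves rounded to 2 decimals)
    expect_lt(max(abs(rep$percent - c(tab$ptv_low_pct[i], tab$ptv_mod_pct[i],
                                      tab$ptv_high_pct[i]))), 0.0101)
  }
  # class volumes that partition the target reproduce its total
  expect_equal(sum(c(243.16, 201.39, 173.50)), 618.05)
  rep2 <- measure_subvolumes(c(low = 243.16, mod = 201.39, high = 173.50))
  expect_equal(attr(rep2, "total_ml"), 618.05)
  expect_equal(sum(rep2$percent), 100, tolerance = 0.05)

  rep3 <- measure_subvolumes(c(high = 37.5))
  expect_equal(rep3$percent, 100)
})

test_that("measurement agrees with voxel counts and spacing", {
  fx <- make_partition_fixture()
  part <- partition_subvolumes(fx$vol, fx$tumor)
  rep <- measure_subvolumes(part)
  vx_ml <- prod(fx$vol$spacing) / 1000
  for (cl in 1:3)
    expect_equal(rep$ml[cl], sum(part$class_map$labels == cl) * vx_ml)
  expect_equal(sum(rep$percent), 100, tolerance = 1e-9)
})

test_that("margin expansion is a spacing-aware ellipsoidal dilation", {
  dm <- c(25, 25, 25)
  one <- array(FALSE, dim = dm); one[13, 13, 13] <- TRUE
  m <- mask3d(one, c(1, 1, 1))
  expect_identical(expand_margin(m, 0)$labels, m$labels)
  d10 <- expand_margin(m, 10)
  expect_equal(sum(d10$labels), oracle_ball_count(10, c(1, 1, 1)))

  # anisotropic spacing: about 2 slices axially, 8 voxels in-plane
  dm2 <- c(25, 25, 11)
  one2 <- array(FALSE, dim = dm2); one2[13, 13, 6] <- TRUE
  m2 <- mask3d(one2, c(1.17, 1.17, 5))
  d2 <- expand_margin(m2, 10)
  zs <- range(which(apply(d2$labels, 3, sum) > 0))
  expect_equal(zs, c(4, 8))                       # +-2 slices at 5 mm
  xs <- range(which(apply(d2$labels, 1, sum) > 0))
  expect_equal(xs, c(5, 21))                      # +-8 voxels at 1.17 mm
  expect_equal(sum(d2$labels), oracle_ball_count(10, c(1.17, 1.17, 5)))

  # monotone and extensive
  a <- array(FALSE, dim = dm); a[10:12, 10:12, 10:12] <- TRUE
  b <- a; b[10:15, 10:15, 10:15] <- TRUE
  da <- expand_margin(mask3d(a, c(1, 1, 1)), 4)$labels
  db <- expand_margin(mask3d(b, c(1, 1, 1)), 4)$labels
  expect_equal(sum(a & !da), 0L)
  expect_equal(sum(da == 1L & db == 0L), 0L)
})

test_that("per-class planning volumes resolve overlap by priority", {
  fx <- make_partition_fixture()
  part <- partition_subvolumes(fx$vol, fx$tumor)
  ptvs <- subvolume_ptvs(part, 6)
  over <- ptvs$overlapping
  excl <- ptvs$exclusive$labels
  # exclusive map equals the priority composition of the overlapping masks
  expect_true(all(excl[over$high$labels == 1L] == 3L))
  expect_true(all(excl[over$mod$labels == 1L & over$high$labels == 0L] == 2L))
  # each expanded class contains its source class
  for (nm in c("low", "mod", "high")) {
    cl <- mtvseg:::SUBVOL_CLASSES[[nm]]
    expect_equal(sum(part$class_map$labels == cl &
                       over[[nm]]$labels == 0L), 0L)
  }
})
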