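# Stage 1: MIP projection, salient regions, saddle-point separation,
# isocontour ROI, back-projection.

test_that("project_mip equals the per-ray maximum oracle", {
  expect_equal(project_mip(suv_volume(array(0, dim = c(5, 6, 7)),
                                      c(1, 1, 1)), 3)$plane,
               matrix(0, 5, 6))
  # single hot voxel carries its depth
  arr <- array(0, dim = c(6, 7, 8)); arr[3, 4, 5] <- 9
  mip <- project_mip(suv_volume(arr, c(1, 1, 1)), 1)
  expect_equal(mip$plane[4, 5], 9)
  expect_equal(mip$depth[4, 5], 3L)
  set.seed(21)
  for (rep in 1:5) {
    arr <- array(runif(8^3), dim = c(8, 8, 8))
    v <- suv_volume(arr, c(1, 1, 1))
    for (ax in 1:3)
      expect_equal(project_mip(v, ax)$plane, oracle_mip(arr, ax))
  }
})

test_that("salient-region detection separates and flags attachment", {
  tb <- make_twin_blobs(sep = 26, sigma = 3)    # disjoint at level 0.3
  det <- detect_salient_regions(as_mip(tb$plane), tb$p1, 0.3)
  expect_gte(det$n_components, 2L)
  expect_false(det$attached)

  tb2 <- make_twin_blobs(sep = 16, sigma = 5)   # overlapping: one component
  det2 <- detect_salient_regions(as_mip(tb2$plane), tb2$p1, 0.3)
  expect_equal(max(det2$labels[tb2$plane >= 0.3 * max(tb2$plane)]),
               det2$seed_label)
  expect_true(det2$attached)
  expect_equal(det2$neighbour_peak, tb2$p2, tolerance = 2)

  u <- matrix(5, 20, 20)
  detu <- detect_salient_regions(as_mip(u), c(10, 10), 0.3)
  expect_equal(detu$n_components, 1L)
  expect_true(all(detu$seed_mask))

  low <- tb$plane
  expect_error(detect_salient_regions(as_mip(low), c(1, 1), 0.3),
               "lower level_fraction")
})

test_that("saddle value equals the widest-path oracle on twin-blob fixtures", {
  set.seed(22)
  for (rep in 1:20) {
    tb <- make_twin_blobs(h1 = 10, h2 = runif(1, 5, 9.5),
                          sep = runif(1, 14, 24), sigma = runif(1, 3, 5),
                          angle = runif(1, 0, pi))
    sad <- find_saddle_point(as_mip(tb$plane), tb$p1, tb$p2)
    expect_equal(sad$value, oracle_widest_path(tb$plane, tb$p1, tb$p2),
                 tolerance = 1e-12)
    expect_lt(sad$value, min(tb$plane[tb$p1[1], tb$p1[2]],
                             tb$plane[tb$p2[1], tb$p2[2]]))
  }
})

test_that("saddle point: symmetry, planted dip, degenerate input", {
  tb <- make_twin_blobs(h1 = 10, h2 = 10, sep = 20, sigma = 4)
  sad <- find_saddle_point(as_mip(tb$plane), tb$p1, tb$p2)
  # symmetric twin peaks: saddle on the perpendicular bisector midline
  expect_equal(sad$point[1], (tb$p1[1] + tb$p2[1]) / 2, tolerance = 1)

  # monotone ridge with a single engineered dip
  ridge <- matrix(0, 11, 11)
  ridge[3:9, 6] <- 8
  ridge[6, 6] <- 3
  sad2 <- find_saddle_point(as_mip(ridge), c(3, 6), c(9, 6))
  expect_equal(sad2$value, 3)
  expect_equal(sad2$point, c(6, 6))

  expect_error(find_saddle_point(as_mip(ridge), c(3, 6), c(3, 6)), "coincide")
})

test_that("tangent line is perpendicular to the peak axis and separates", {
  mip <- as_mip(matrix(1, 12, 12))
  sep <- tangent_separation(mip, c(5, 1), c(1, 1), c(11, 1))
  # axis-aligned: vertical line through row 5; peaks on opposite sides
  s1 <- mtvseg:::separation_side(sep, matrix(c(1, 1), 1), mip)
  s2 <- mtvseg:::separation_side(sep, matrix(c(11, 1), 1), mip)
  expect_true(s1 > 0 && s2 < 0)
  expect_equal(abs(sep$normal), c(1, 0))

  # 90-degree rotated scene rotates the tangent
  sep_rot <- tangent_separation(mip, c(1, 5), c(1, 1), c(1, 11))
  expect_equal(abs(sep_rot$normal), c(0, 1))

  # oblique peaks: normal parallel to the peak-to-peak direction
  sep_ob <- tangent_separation(mip, c(5, 4), c(1, 1), c(9, 7))
  expect_equal(abs(sep_ob$normal), abs(c(8, 6) / 10), tolerance = 1e-12)

  expect_error(tangent_separation(mip, c(5, 4), c(2, 2), c(2, 2)),
               "degenerate")
})

test_that("isocontour ROI honours the seed component and the half-plane", {
  tb <- make_twin_blobs(h1 = 10, h2 = 8, sep = 18, sigma = 4)
  mip <- as_mip(tb$plane)
  sad <- find_saddle_point(mip, tb$p1, tb$p2)
  sep <- tangent_separation(mip, sad, tb$p1, tb$p2)
  roi <- isocontour_roi(mip, sad$value, tb$p1, sep)
  expect_true(roi[tb$p1[1], tb$p1[2]])
  # the other blob's core is excluded entirely
  other_core <- tb$plane >= 0.9 * tb$plane[tb$p2[1], tb$p2[2]] &
    !(tb$plane >= 0.9 * tb$plane[tb$p1[1], tb$p1[2]])
  other_core[seq_len(nrow(roi)) < sad$point[1], ] <- FALSE
  expect_equal(sum(roi & other_core), 0L)

  # isolated blob, no tangent
  roi2 <- isocontour_roi(mip, 0.3 * max(tb$plane), tb$p1, NULL)
  expect_true(roi2[tb$p1[1], tb$p1[2]])

  # level at the plane max leaves only the argmax point(s)
  roi3 <- isocontour_roi(mip, max(tb$plane),
                         as.integer(which(tb$plane == max(tb$plane),
                                          arr.ind = TRUE)[1, ]), NULL)
  expect_equal(sum(roi3), sum(tb$plane == max(tb$plane)))

  expect_error(isocontour_roi(mip, max(tb$plane) + 1, tb$p1, NULL),
               "below the contour level")
})

test_that("back-projection intersects extrusions and keeps superset-ness", {
  dm <- c(8L, 9L, 10L)
  rx <- matrix(FALSE, 9, 10); rx[2:5, 3:7] <- TRUE   # axis 1 roi (y,z)
  ry <- matrix(FALSE, 8, 10); ry[3:6, 3:7] <- TRUE   # axis 2 roi (x,z)
  rz <- matrix(FALSE, 8, 9);  rz[3:6, 2:5] <- TRUE   # axis 3 roi (x,y)
  ms <- backproject_3dms(list(rx, ry, rz), dm, axes = 1:3)
  box <- array(FALSE, dim = dm); box[3:6, 2:5, 3:7] <- TRUE
  expect_identical(mtvseg:::mask_fg(ms), box)

  full <- backproject_3dms(list(matrix(TRUE, 9, 10), matrix(TRUE, 8, 10)),
                           dm, axes = 1:2)
  expect_true(all(mtvseg:::mask_fg(full)))

  ry2 <- matrix(FALSE, 8, 10); ry2[7:8, 8:10] <- TRUE
  expect_error(backproject_3dms(list(rz = rz, ry = ry2), dm, axes = c(3, 2)),
               "add projection directions")

  # sphere phantom: back-projected rois form a superset of the truth
  spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing = c(2, 2, 2),
                       tumor_radii_mm = c(16, 15, 14))
  ph <- generate_phantom(spec)
  ms2 <- extract_3dms(ph$vol, ph$seed)
  expect_equal(sum(ph$truth_tumor$labels == 1L & ms2$labels == 0L), 0L)
})

test_that("extract_3dms contains the seed and the tumor projection support", {
  ctl <- mtv_control()
  spec <- phantom_spec(grid_shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
                       tumor_radii_mm = c(15, 13, 12), organ = FALSE)
  ph <- generate_phantom(spec)
  ms <- extract_3dms(ph$vol, ph$seed, ctl)
  expect_true(ms$labels[ph$seed[1], ph$seed[2], ph$seed[3]] == 1L)
  cover <- sum(ms$labels == 1L & ph$truth_tumor$labels == 1L) /
    sum(ph$truth_tumor$labels == 1L)
  expect_gte(cover, 0.99)

  # attached case: the masking surface avoids the organ core entirely
  spec2 <- phantom_spec(grid_shape = c(80, 80, 80), spacing = c(1.5, 1.5, 1.5),
                        tumor_radii_mm = c(15, 13, 12), organ = TRUE)
  ph2 <- generate_phantom(spec2)
  ms2 <- extract_3dms(ph2$vol, ph2$seed, ctl)
  expect_equal(sum(ms2$labels == 1L & ph2$organ_core$labels == 1L), 0L)
  cover2 <- sum(ms2$labels == 1L & ph2$truth_tumor$labels == 1L) /
    sum(ph2$truth_tumor$labels == 1L)
  expect_gte(cover2, 0.99)

  # stage 1 does not depend on the affinity beta
  ms3 <- extract_3dms(ph2$vol, ph2$seed, mtv_control(beta_magnitude = 10))
  expect_identical(ms3$labels, ms2$labels)
})
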