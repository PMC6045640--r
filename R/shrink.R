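# Stage 2: shrink the 3-D masking surface onto the tumor boundary with a
# hill-climbing front whose stopping rule joins Gaussian-filtered gradient
# magnitude with local mean-uptake (box-mean SUV) affinity.

#' Gaussian-filtered gradient magnitude
#'
#' `g = G * |grad f|`: the Euclidean norm of central-difference gradients of
#' the SUV field (one-sided at the volume border, in voxel units), smoothed
#' with a rotationally symmetric Gaussian of standard deviation `sigma`
#' voxels. Smoothing suppresses noise while preserving the salient boundary
#' ridge on which the shrinking front stops.
#'
#' @param vol an [suv_volume()] or 3-D array.
#' @param sigma Gaussian standard deviation in voxels (> 0). Default 1.5.
#' @return 3-D array `g >= 0` on the same grid.
#' @export
gaussian_gradient_magnitude <- function(vol, sigma = 1.5) {
  if (sigma <= 0) stop("`sigma` must be positive")
  f <- if (inherits(vol, "suv_volume")) vol$data else vol
  g2 <- array(0, dim = dim(f))
  for (ax in 1:3) {
    if (dim(f)[ax] == 1L) next
    d <- central_diff(f, ax)
    g2 <- g2 + d * d
  }
  gauss_smooth(sqrt(g2), sigma)
}

# central differences along an axis, one-sided at the borders, voxel units
central_diff <- function(f, ax) {
  dm <- dim(f)
  n <- dm[ax]
  idx_hi <- pmin(seq_len(n) + 1L, n)
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  den <- idx_hi - idx_lo # 2 in the interior, 1 at the borders
  slice <- function(ii) {
    switch(ax,
           f[ii, , , drop = FALSE],
           f[, ii, , drop = FALSE],
           f[, , ii, drop = FALSE])
  }
  d <- slice(idx_hi) - slice(idx_lo)
  shp <- c(1L, 1L, 1L); shp[ax] <- n
  sweep(d, ax, den, `/`)
}

#' Neighbourhood mean SUV
#'
#' The average SUV within the `(2r+1)^3` box centred at each voxel, with the
#' box clipped to the volume bounds (the mean is over in-bounds voxels only).
#'
#' @param vol an [suv_volume()] or 3-D array.
#' @param box_radius half-width of the box, at least 1. Default 1 (3x3x3 box).
#' @return 3-D array of local means.
#' @export
neighborhood_mean <- function(vol, box_radius = 1L) {
  box_radius <- as.integer(box_radius)
  if (box_radius < 1L) stop("`box_radius` must be >= 1")
  f <- if (inherits(vol, "suv_volume")) vol$data else vol
  box_mean(f, box_radius)
}

#' Joint gradient/intensity affinity of two adjacent voxels
#'
#' `phi(v_i, v_j) = exp(-beta * (g_j - g_i))` where the sign of `beta` is set
#' by the local mean uptake: `beta = +|beta|` when `fbar_i > fbar_j`,
#' `beta = -|beta|` otherwise (ties included). The exponent is clamped at
#' +/-700 to avoid overflow. Only the sign of `beta` matters for threshold
#' comparisons against `tau = 1`, which is why the magnitude has no effect on
#' the segmentation.
#'
#' @param g_i,g_j Gaussian-filtered gradient magnitudes at the two voxels.
#' @param fbar_i,fbar_j box-mean SUV at the two voxels.
#' @param beta_magnitude positive magnitude of `beta`. Default 60.
#' @return Scalar affinity `phi > 0`. Vectorized over its arguments.
#' @export
joint_affinity <- function(g_i, g_j, fbar_i, fbar_j, beta_magnitude = 60) {
  if (any(beta_magnitude <= 0)) stop("`beta_magnitude` must be positive")
  beta <- ifelse(fbar_i > fbar_j, beta_magnitude, -beta_magnitude)
  ex <- -beta * (g_j - g_i)
  ex <- pmin(pmax(ex, -700), 700)
  exp(ex)
}

#' Hill-climbing shrink of the masking surface (stage 2)
#'
#' An inward-moving front starts at the surface of the 3-D masking surface
#' `ms` and is processed in descending order of physical distance to the
#' seed. For a front voxel `v_i` with inward neighbour `v_j` (the adjacent
#' in-mask voxel closest to the seed; ties broken by higher mean uptake, then
#' by index), the front freezes -- the boundary has been reached -- when mean
#' uptake increases inward (`fbar_j > fbar_i`) and the affinity of the uphill
#' move satisfies `exp(-|beta| (g_j - g_i)) >= tau`, i.e. the smoothed
#' gradient-magnitude ridge has just been crossed. Otherwise `v_i` is
#' relabelled background and the front advances. Frozen voxels and everything
#' inward of them form the tumor.
#'
#' The raw carved mask is then regularized: a one-voxel morphological opening
#' removes speckle attachments left by noise-induced freezes, the seed's
#' connected component is kept, and fully enclosed cavities are filled so
#' that low-uptake (necrotic) interiors are never excluded from the tumor.
#'
#' @param vol an [suv_volume()].
#' @param ms a [mask3d()] 3-D masking surface containing the seed.
#' @param seed a [seed_voxel()] or integer length-3 index.
#' @param control a [mtv_control()] list (keys `beta_magnitude`, `sigma`,
#'   `box_radius`, `tau`, `neighbour_connectivity`, `regularize`).
#' @return A [mask3d()] tumor mask `T` with `T` a subset of `ms`, connected,
#'   containing the seed. Attribute `"carve"` holds front statistics.
#' @export
hill_climb_shrink <- function(vol, ms, seed, control = mtv_control()) {
  seed <- seed_voxel(seed, vol)
  fg <- mask_fg(ms, dim(vol$data))
  if (!fg[seed[1], seed[2], seed[3]])
    stop("the masking surface does not contain the seed")
  g <- gaussian_gradient_magnitude(vol, control$sigma)
  fbar <- neighborhood_mean(vol, control$box_radius)
  status <- .hill_climb_cpp(as.double(fbar), as.double(g),
                            as.integer(dim(vol$data)), as.logical(fg),
                            as.integer(seed), as.double(vol$spacing),
                            as.double(control$beta_magnitude),
                            as.double(control$tau),
                            as.integer(control$neighbour_connectivity))
  raw <- array(status == 1L | status == 4L, dim = dim(vol$data))
  out <- raw
  if (isTRUE(control$regularize)) {
    opened <- dilate_mask(erode_mask(out, cross_offsets()), cross_offsets())
    # never lose the seed to the opening
    if (!opened[seed[1], seed[2], seed[3]]) opened[seed[1], seed[2], seed[3]] <- TRUE
    out <- opened & out
  }
  out <- seed_component(out, seed, 26L)
  out <- fill_holes(out)
  out <- out & fg # regularization must not escape the masking surface
  if (sum(out) < 2L) stop("no boundary found; check seed/3D-MS")
  res <- mask3d(out, vol$spacing, vol$origin)
  attr(res, "carve") <- list(ms_voxels = sum(fg), frozen = sum(status == 4L),
                             removed = sum(status == 3L), tumor_voxels = sum(out))
  res
}

#' Segment the target tumor (full two-stage pipeline)
#'
#' Runs stage 1 ([extract_3dms()]) then stage 2 ([hill_climb_shrink()]) and
#' returns a classed result with the tumor mask, the masking surface, and a
#' provenance record (control parameters, per-stage timings, boundary-SUV
#' summary).
#'
#' @param vol an [suv_volume()].
#' @param seed a [seed_voxel()] or integer length-3 voxel index.
#' @param control a [mtv_control()].
#' @return Object of class `mtv_seg` with elements `tumor` ([mask3d()]),
#'   `ms`, `seed`, `control`, `suv_max`, `boundary_suv`, `timings`, `vol`.
#' @seealso [partition_subvolumes()], [dice()], [hausdorff()]
#' @export
segment_tumor <- function(vol, seed, control = mtv_control()) {
  seed <- seed_voxel(seed, vol)
  t0 <- proc.time()[["elapsed"]]
  ms <- extract_3dms(vol, seed, control)
  t1 <- proc.time()[["elapsed"]]
  tumor <- hill_climb_shrink(vol, ms, seed, control)
  t2 <- proc.time()[["elapsed"]]
  fg <- tumor$labels != 0L
  surf <- fg & !erode_mask(fg, cross_offsets())
  smax <- max(vol$data[fg])
  structure(list(tumor = tumor, ms = ms, seed = seed, control = control,
                 suv_max = smax,
                 boundary_suv = vol$data[surf],
                 timings = c(stage1 = t1 - t0, stage2 = t2 - t1),
                 vol = vol),
            class = "mtv_seg")
}

#' Fixed-threshold region-growing baseline (RG40 / RG50)
#'
#' The classical comparison method: within a fixed bounding box of
#' 60 x 60 x 20 voxels centred at the seed (clipped to the volume), the
#' connected component containing the seed of
#' `{f >= fraction * SUVmax(box)}`. `fraction = 0.40` gives RG40 and
#' `0.50` gives RG50.
#'
#' @param vol an [suv_volume()].
#' @param seed a [seed_voxel()] or integer length-3 index.
#' @param fraction threshold fraction of the in-box SUVmax, in (0, 1).
#' @param box integer length-3 bounding-box size in voxels.
#' @return A [mask3d()].
#' @export
threshold_baseline <- function(vol, seed, fraction = 0.40,
                               box = c(60L, 60L, 20L)) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  seed <- seed_voxel(seed, vol)
  dm <- dim(vol$data)
  half <- floor(box / 2)
  lo <- pmax(seed - half, 1L)
  hi <- pmin(seed + half, dm)
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  thr <- fraction * max(sub)
  if (vol$data[seed[1], seed[2], seed[3]] < thr)
    stop("seed SUV lies below the threshold; region growing yields an empty result")
  fg_sub <- sub >= thr
  seed_sub <- as.integer(seed) - lo + 1L
  comp <- seed_component(fg_sub, seed_sub, 26L)
  out <- array(FALSE, dim = dm)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp
  mask3d(out, vol$spacing, vol$origin)
}
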