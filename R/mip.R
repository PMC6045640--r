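# Stage 1: separation of the target tumor from adjacent high-uptake
# structures via per-axis maximum-intensity projections (MIPs). On each MIP a
# saddle point between the tumor peak and the neighbouring peak defines an
# isocontour and a tangent line; the per-axis ROI masks are back-projected and
# intersected to form the 3-D masking surface (3D-MS).

#' Maximum-intensity projection along one axis
#'
#' Projects a volume along an axis, keeping for every ray both the maximum SUV
#' and the (first) index attaining it.
#'
#' @param vol an [suv_volume()].
#' @param axis projection axis, 1 (x), 2 (y) or 3 (z). The plane keeps the two
#'   remaining axes in increasing order: axis 1 -> (y, z), 2 -> (x, z),
#'   3 -> (x, y).
#' @return Object of class `mip_image` with fields `plane` (matrix of per-ray
#'   maxima), `depth` (arg-max index along the projected axis), `axis`,
#'   `spacing2` (mm per plane axis) and `spacing_axis`.
#' @export
project_mip <- function(vol, axis) {
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3")
  dm <- dim(vol$data)
  if (dm[axis] < 1L) stop("volume is degenerate along the projection axis")
  keep <- setdiff(1:3, axis)
  plane <- apply(vol$data, keep, max)
  depth <- apply(vol$data, keep, which.max)
  structure(list(plane = plane, depth = depth, axis = axis,
                 spacing2 = vol$spacing[keep],
                 spacing_axis = vol$spacing[axis]),
            class = "mip_image")
}

# plane-coordinate physical positions (mm), unit spacing when spacing2 absent
plane_mm <- function(idx2, mip) {
  sp <- if (is.null(mip$spacing2)) c(1, 1) else mip$spacing2
  if (is.null(dim(idx2))) idx2 <- matrix(idx2, nrow = 1)
  sweep(idx2 - 1, 2, sp, `*`)
}

#' Salient-region detection on a MIP image
#'
#' High-uptake tissues stand out from the background of a MIP plane. The plane
#' is thresholded at `level_fraction` of its maximum and 8-connected
#' components are labelled. The component containing the projected seed is
#' reported, together with a neighbouring high-uptake peak inside that same
#' component (if any): the signature of a tumor attached to another hot
#' structure, which then requires saddle-point separation.
#'
#' The seed's own peak is found by steepest ascent from the seed on a lightly
#' smoothed copy of the plane. A neighbour peak is a regional maximum of the
#' smoothed plane inside the seed component, at least `min_distance_mm` from
#' the seed peak and at least `min_height_frac` of the seed peak's height.
#'
#' @param mip a `mip_image` from [project_mip()].
#' @param seed2d integer length-2 plane index of the projected seed.
#' @param level_fraction threshold as a fraction of the plane maximum,
#'   in (0, 1). Default 0.30.
#' @param min_distance_mm minimum seed-peak-to-neighbour-peak distance (mm).
#' @param min_height_frac minimum neighbour peak height as a fraction of the
#'   seed peak height.
#' @return List with `labels` (component label matrix), `seed_label`,
#'   `seed_mask` (logical matrix of the seed component), `n_components`,
#'   `seed_peak`, `neighbour_peak` (`NULL` when isolated), and `attached`.
#' @export
detect_salient_regions <- function(mip, seed2d, level_fraction = 0.3,
                                   min_distance_mm = 15,
                                   min_height_frac = 0.5) {
  if (level_fraction <= 0 || level_fraction >= 1)
    stop("`level_fraction` must lie in (0, 1)")
  plane <- mip$plane
  seed2d <- as.integer(seed2d)
  if (any(seed2d < 1L) || any(seed2d > dim(plane)))
    stop("seed2d lies outside the MIP plane")
  level <- level_fraction * max(plane)
  if (plane[seed2d[1], seed2d[2]] < level)
    stop("seed is not salient at level_fraction = ", level_fraction,
         "; use a lower level_fraction")
  fg <- plane >= level
  labels <- label_components(fg, 26L)
  seed_label <- labels[seed2d[1], seed2d[2]]
  seed_mask <- labels == seed_label
  smooth <- gauss_smooth(array(plane, dim = c(dim(plane), 1L)), c(1, 1, 0))[, , 1]
  seed_peak <- ascend2d(smooth, seed2d, seed_mask)
  nb <- neighbour_peak2d(smooth, seed_mask, seed_peak, mip,
                         min_distance_mm, min_height_frac)
  list(labels = labels, seed_label = seed_label, seed_mask = seed_mask,
       n_components = max(labels), level = level,
       seed_peak = seed_peak, neighbour_peak = nb, attached = !is.null(nb))
}

# steepest-ascent walk on a matrix restricted to `mask`, 8-connectivity
ascend2d <- function(plane, start, mask) {
  p <- as.integer(start)
  dm <- dim(plane)
  repeat {
    best <- p
    bestv <- plane[p[1], p[2]]
    for (a in -1:1) for (b in -1:1) {
      q <- p + c(a, b)
      if (any(q < 1L) || q[1] > dm[1] || q[2] > dm[2]) next
      if (!mask[q[1], q[2]]) next
      if (plane[q[1], q[2]] > bestv) { bestv <- plane[q[1], q[2]]; best <- q }
    }
    if (all(best == p)) return(p)
    p <- best
  }
}

# highest regional maximum of `plane` within seed component, farther than
# min_distance_mm from the seed peak and at least min_height_frac of its height
neighbour_peak2d <- function(plane, seed_mask, seed_peak, mip,
                             min_distance_mm, min_height_frac) {
  dm <- dim(plane)
  # regional maxima by shifted comparison (plateaus count; ties resolved later)
  ismax <- matrix(TRUE, dm[1], dm[2])
  for (a in -1:1) for (b in -1:1) {
    if (a == 0 && b == 0) next
    sh <- matrix(-Inf, dm[1], dm[2])
    si <- max(1, 1 + a):min(dm[1], dm[1] + a)
    sj <- max(1, 1 + b):min(dm[2], dm[2] + b)
    sh[si, sj] <- plane[si - a, sj - b]
    ismax <- ismax & (plane >= sh)
  }
  cand <- which(ismax & seed_mask, arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  pk_mm <- plane_mm(matrix(seed_peak, 1), mip)
  d <- sqrt(rowSums((plane_mm(cand, mip) -
                     matrix(pk_mm, nrow(cand), 2, byrow = TRUE))^2))
  h <- plane[cand]
  keep <- d >= min_distance_mm & h >= min_height_frac * plane[seed_peak[1], seed_peak[2]]
  if (!any(keep)) return(NULL)
  cand <- cand[keep, , drop = FALSE]
  h <- h[keep]
  best <- which.max(h)
  as.integer(cand[best, ])
}

#' Saddle point between two attached peaks on a MIP plane
#'
#' The saddle is the highest pass between the two peaks: the point realizing
#' the maximum over all 8-connected paths of the minimum intensity along the
#' path. It is computed by a descending-threshold merge: pixels are activated
#' in decreasing intensity order with union-find merging; the pixel whose
#' activation first connects the two peaks is the saddle, and its intensity is
#' the saddle value.
#'
#' @param mip a `mip_image`.
#' @param seed2d plane index of the seed-side peak.
#' @param other_max plane index of the neighbouring peak.
#' @return List with `point` (plane index) and `value` (plane intensity).
#' @export
find_saddle_point <- function(mip, seed2d, other_max) {
  plane <- mip$plane
  dm <- dim(plane)
  a <- as.integer(seed2d); b <- as.integer(other_max)
  if (all(a == b)) stop("the two peaks coincide")
  n <- length(plane)
  ord <- order(as.vector(plane), decreasing = TRUE)
  parent <- integer(n) # 0 = not yet activated
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  la <- a[1] + (a[2] - 1L) * dm[1]
  lb <- b[1] + (b[2] - 1L) * dm[1]
  for (v in ord) {
    parent[v] <- v
    i <- ((v - 1L) %% dm[1]) + 1L
    j <- ((v - 1L) %/% dm[1]) + 1L
    for (da in -1:1) for (db in -1:1) {
      if (da == 0 && db == 0) next
      ii <- i + da; jj <- j + db
      if (ii < 1L || jj < 1L || ii > dm[1] || jj > dm[2]) next
      w <- ii + (jj - 1L) * dm[1]
      if (parent[w] == 0L) next
      rw <- find(w); rv <- find(v)
      if (rw != rv) parent[rw] <- rv
    }
    if (parent[la] != 0L && parent[lb] != 0L && find(la) == find(lb)) {
      return(list(point = c(i, j), value = plane[i, j]))
    }
  }
  stop("peaks lie in different components; no saddle exists")
}

#' Tangent line separating two attached salient regions
#'
#' The separating line passes through the saddle point and is perpendicular to
#' the segment joining the two peaks (geometry in physical mm, so anisotropic
#' plane spacing is respected). The seed peak and the other peak fall on
#' opposite sides.
#'
#' @param mip a `mip_image`.
#' @param saddle plane index of the saddle point (or result of
#'   [find_saddle_point()]).
#' @param seed_peak,other_peak plane indices of the two peaks.
#' @return Object of class `separation2d`: `point_mm` (saddle position),
#'   `normal` (unit normal in mm space, pointing to the seed side),
#'   `saddle` (index), `saddle_value`.
#' @export
tangent_separation <- function(mip, saddle, seed_peak, other_peak) {
  if (is.list(saddle)) { sv <- saddle$value; saddle <- saddle$point }
  else sv <- mip$plane[saddle[1], saddle[2]]
  p1 <- as.numeric(plane_mm(matrix(as.integer(seed_peak), 1), mip))
  p2 <- as.numeric(plane_mm(matrix(as.integer(other_peak), 1), mip))
  dir <- p1 - p2
  nr <- sqrt(sum(dir^2))
  if (nr == 0) stop("the two peaks coincide; separation direction is degenerate")
  structure(list(point_mm = as.numeric(plane_mm(matrix(as.integer(saddle), 1), mip)),
                 normal = dir / nr, saddle = as.integer(saddle),
                 saddle_value = sv),
            class = "separation2d")
}

# signed side of plane indices relative to a separation line (>0 = seed side)
separation_side <- function(sep, idx2, mip) {
  pm <- plane_mm(idx2, mip)
  as.numeric((pm - matrix(sep$point_mm, nrow(idx2), 2, byrow = TRUE)) %*% sep$normal)
}

#' Isocontour ROI mask on a MIP plane
#'
#' The connected component of `{plane >= level}` containing the seed,
#' intersected (when a separation is supplied) with the seed-side half-plane
#' of the tangent line. Points on the line itself count as seed-side, so the
#' saddle remains inside the ROI.
#'
#' @param mip a `mip_image`.
#' @param level contour level (absolute SUV), typically the saddle value.
#' @param seed2d plane index of the projected seed.
#' @param separation optional `separation2d` from [tangent_separation()].
#' @return Logical matrix ROI containing `seed2d`.
#' @export
isocontour_roi <- function(mip, level, seed2d, separation = NULL) {
  if (level <= 0) stop("contour level must be positive")
  plane <- mip$plane
  seed2d <- as.integer(seed2d)
  if (plane[seed2d[1], seed2d[2]] < level)
    stop("seed lies below the contour level; it must be inside the isocontour")
  fg <- plane >= level
  if (!is.null(separation)) {
    idx <- which(fg, arr.ind = TRUE)
    side <- separation_side(separation, idx, mip)
    fg[idx[side < 0, , drop = FALSE]] <- FALSE
  }
  lab <- label_components(fg, 26L)
  roi <- lab == lab[seed2d[1], seed2d[2]]
  roi
}

#' Back-project per-axis ROI masks to a 3-D mask
#'
#' Each ROI is extruded along its own projection axis; the 3D-MS mask is the
#' intersection of the extrusions (the tightest set consistent with all
#' projections, guaranteed to contain any object reproducing those
#' projections).
#'
#' @param rois named or ordered list of logical ROI matrices; element names or
#'   the `axes` argument give the projection axis of each.
#' @param dim3 integer length-3 dimensions of the target volume.
#' @param axes integer vector of projection axes matching `rois`.
#' @param spacing,origin grid geometry for the returned [mask3d()].
#' @return A [mask3d()] whose boundary is the 3-D masking surface.
#' @export
backproject_3dms <- function(rois, dim3, axes = seq_along(rois),
                             spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(rois) < 1L || length(rois) > 3L)
    stop("between 1 and 3 ROI masks are required")
  dim3 <- as.integer(dim3)
  acc <- array(TRUE, dim = dim3)
  for (t in seq_along(rois)) {
    ax <- axes[t]
    roi <- rois[[t]]
    keep <- setdiff(1:3, ax)
    if (!identical(dim(roi), dim3[keep]))
      stop("ROI for axis ", ax, " does not match the volume grid")
    ext <- array(FALSE, dim = dim3)
    if (ax == 1) ext[] <- rep(as.vector(roi), each = dim3[1])
    if (ax == 2) ext <- aperm(array(rep(as.vector(roi), each = dim3[2]),
                                    dim = c(dim3[2], dim3[1], dim3[3])),
                              c(2, 1, 3))
    if (ax == 3) ext[] <- rep(as.vector(roi), times = dim3[3]) |>
        array(dim = dim3) |> as.vector()
    acc <- acc & ext
  }
  if (!any(acc))
    stop("projections inconsistent; add projection directions")
  mask3d(acc, spacing, origin)
}

#' Extract the 3-D masking surface (stage 1)
#'
#' Orchestrates, per projection axis: MIP projection, salient-region
#' detection, and -- on axes where the seed's component also contains a
#' neighbouring high-uptake peak -- saddle-point location, tangent-line
#' separation and isocontour ROI extraction. The per-axis ROIs are
#' back-projected and intersected into the 3D-MS. On attached axes the
#' contour level is `min(saddle value, level_fraction * plane max)` so that
#' the ROI keeps the full tumor silhouette while the tangent line removes the
#' neighbouring structure.
#'
#' @param vol an [suv_volume()].
#' @param seed a [seed_voxel()] or integer length-3 voxel index.
#' @param control a [mtv_control()] list (keys `level_fraction`,
#'   `neighbour_min_distance_mm`, `neighbour_min_height_frac`,
#'   `projection_axes`).
#' @return A [mask3d()] with attribute `"stages"`: per-axis diagnostics
#'   (attachment flag, saddle, contour level).
#' @export
extract_3dms <- function(vol, seed, control = mtv_control()) {
  seed <- seed_voxel(seed, vol)
  axes <- control$projection_axes
  rois <- list()
  stages <- list()
  for (ax in axes) {
    mip <- project_mip(vol, ax)
    keep <- setdiff(1:3, ax)
    seed2d <- as.integer(seed)[keep]
    det <- tryCatch(
      detect_salient_regions(mip, seed2d, control$level_fraction,
                             control$neighbour_min_distance_mm,
                             control$neighbour_min_height_frac),
      error = function(e) stop("axis ", ax, ": ", conditionMessage(e)))
    attached <- det$attached
    if (attached) {
      sad <- find_saddle_point(mip, det$seed_peak, det$neighbour_peak)
      # prominence test: a separate structure has a connecting pass well
      # below both peaks; a shallow dip is internal heterogeneity of one
      # structure (e.g. a necrotic core seen in projection) and must not be
      # separated
      floor_peak <- min(mip$plane[det$seed_peak[1], det$seed_peak[2]],
                        mip$plane[det$neighbour_peak[1], det$neighbour_peak[2]])
      if (sad$value >= control$saddle_prominence_frac * floor_peak)
        attached <- FALSE
    }
    if (attached) {
      sep <- tangent_separation(mip, sad, det$seed_peak, det$neighbour_peak)
      level <- min(sad$value, det$level)
      roi <- tryCatch(isocontour_roi(mip, level, seed2d, sep),
                      error = function(e) stop("axis ", ax, ": ",
                                               conditionMessage(e)))
      stages[[as.character(ax)]] <- list(attached = TRUE, saddle = sad,
                                         level = level)
    } else {
      roi <- det$seed_mask
      stages[[as.character(ax)]] <- list(attached = FALSE, level = det$level)
    }
    rois[[length(rois) + 1L]] <- roi
  }
  ms <- backproject_3dms(rois, dim(vol$data), axes = axes,
                         spacing = vol$spacing, origin = vol$origin)
  attr(ms, "stages") <- stages
  ms
}
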