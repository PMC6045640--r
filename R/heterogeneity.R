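# Metabolic sub-volume partitioning of the segmented tumor for
# dose-escalation planning: low / moderate / high uptake classes by
# fractional-SUVmax ranges, a minimum-size merge rule matched to the
# treatment-planning calculation grid, volume/percent reporting, and
# margin-expanded planning volumes.

SUBVOL_CLASSES <- c(low = 1L, mod = 2L, high = 3L)
SUBVOL_BREAKS <- c(0, 0.25, 0.50, 1.00) # half-open (lo, hi] fractions of SUVmax

#' Partition a tumor into metabolic sub-volumes
#'
#' Classifies every tumor voxel into low / moderate / high metabolic activity
#' by the half-open SUV ranges `(0, 25%]`, `(25%, 50%]` and `(50%, 100%]` of
#' the SUVmax inside the segmented tumor. A voxel at exactly 25 % SUVmax is
#' class low; just above, class moderate (the upper bracket is closed).
#'
#' @param vol an [suv_volume()].
#' @param tumor a [mask3d()] tumor mask (or an `mtv_seg` result).
#' @return Object of class `subvol_partition`: `class_map` ([mask3d()] with
#'   labels 0 = outside, 1 = low, 2 = mod, 3 = high), `suv_max_ref`,
#'   `components` (data frame: class, component id, voxel count, volume ml,
#'   mean SUV), `spacing`, plus internal fields used by the merge rule.
#' @export
partition_subvolumes <- function(vol, tumor) {
  if (inherits(tumor, "mtv_seg")) tumor <- tumor$tumor
  fg <- mask_fg(tumor, dim(vol$data))
  if (!any(fg)) stop("tumor mask is empty")
  smax <- max(vol$data[fg])
  if (smax <= 0) stop("SUVmax inside the tumor must be positive")
  frac <- vol$data / smax
  cls <- array(0L, dim = dim(vol$data))
  cls[fg] <- 1L + (frac[fg] > SUBVOL_BREAKS[2]) + (frac[fg] > SUBVOL_BREAKS[3])
  part <- structure(list(class_map = mask3d(cls, vol$spacing, vol$origin,
                                            label_set = 0:3),
                         suv_max_ref = smax,
                         spacing = vol$spacing,
                         suv = vol$data,
                         merges = NULL),
                    class = "subvol_partition")
  part$components <- subvol_components(part)
  part
}

# inventory of 26-connected components per class
subvol_components <- function(part) {
  cls <- part$class_map$labels
  vx_ml <- prod(part$spacing) / 1000
  out <- list()
  for (cl in SUBVOL_CLASSES) {
    lab <- label_components(cls == cl, 26L)
    nc <- max(lab)
    if (nc == 0) next
    cnt <- tabulate(lab[lab > 0L], nbins = nc)
    msuv <- vapply(seq_len(nc), function(i) mean(part$suv[lab == i]), 0)
    out[[length(out) + 1L]] <-
      data.frame(class = names(SUBVOL_CLASSES)[SUBVOL_CLASSES == cl],
                 component = seq_len(nc), voxels = cnt,
                 volume_ml = cnt * vx_ml, mean_suv = msuv)
  }
  if (!length(out))
    return(data.frame(class = character(), component = integer(),
                      voxels = integer(), volume_ml = numeric(),
                      mean_suv = numeric()))
  do.call(rbind, out)
}

#' Merge sub-volume components below the planning-grid size
#'
#' A sub-volume component smaller than `min_voxels` (default 25, the
#' 5 x 5 x 1 calculation-grid cell of the planning system) is not counted as
#' an isolated sub-volume: it is relabelled to the class of its nearest
#' neighbouring component. "Nearest" is the component sharing the largest
#' face-adjacent boundary area; if nothing touches, the component with the
#' smallest centroid distance in mm; remaining ties go to the class whose SUV
#' range midpoint is closest to the small component's mean SUV. Merging
#' iterates, smallest component first, until no component is below the limit
#' or only one component remains.
#'
#' @param part a `subvol_partition`.
#' @param min_voxels minimum component size in voxels. Default 25.
#' @return The partition with small components merged; `$merges` audits each
#'   merge event (class, size, target class).
#' @export
merge_small_components <- function(part, min_voxels = 25L) {
  min_voxels <- as.integer(min_voxels)
  cls <- part$class_map$labels
  vx_ml <- prod(part$spacing) / 1000
  merges <- list()
  repeat {
    # joint labelling: one label per (class, component)
    joint <- array(0L, dim = dim(cls))
    nxt <- 0L
    comp_class <- integer()
    for (cl in SUBVOL_CLASSES) {
      l <- label_components(cls == cl, 26L)
      k <- max(l)
      if (k > 0) {
        joint[l > 0L] <- l[l > 0L] + nxt
        comp_class <- c(comp_class, rep(cl, k))
        nxt <- nxt + k
      }
    }
    if (nxt <= 1L) break
    cnt <- tabulate(joint[joint > 0L], nbins = nxt)
    small <- which(cnt < min_voxels)
    if (!length(small)) break
    target <- small[order(cnt[small], small)][1] # smallest first, then id
    tv <- joint == target
    # neighbour components by face adjacency
    nb_counts <- integer(nxt)
    dm <- dim(cls)
    idx <- which(tv, arr.ind = TRUE)
    for (d in 1:3) for (s in c(-1L, 1L)) {
      sh <- idx
      sh[, d] <- sh[, d] + s
      ok <- sh[, d] >= 1L & sh[, d] <= dm[d]
      if (!any(ok)) next
      nb <- joint[sh[ok, , drop = FALSE]]
      nb <- nb[nb > 0L & nb != target]
      if (length(nb)) {
        t <- tabulate(nb, nbins = nxt)
        nb_counts <- nb_counts + t
      }
    }
    cand <- which(nb_counts > 0L)
    if (length(cand)) {
      best_area <- max(nb_counts[cand])
      cand <- cand[nb_counts[cand] == best_area]
    } else {
      # nothing touches: smallest centroid distance in mm
      cen <- colMeans(voxel_mm(idx, part$spacing))
      others <- setdiff(seq_len(nxt), target)
      dist <- vapply(others, function(o) {
        oi <- which(joint == o, arr.ind = TRUE)
        oc <- colMeans(voxel_mm(oi, part$spacing))
        sqrt(sum((oc - cen)^2))
      }, 0)
      cand <- others[dist == min(dist)]
    }
    if (length(cand) > 1L) {
      # tie-break: class SUV-range midpoint closest to the component's mean SUV
      msuv <- mean(part$suv[tv]) / part$suv_max_ref
      mid <- (SUBVOL_BREAKS[-4] + SUBVOL_BREAKS[-1]) / 2
      dmid <- abs(mid[comp_class[cand]] - msuv)
      cand <- cand[order(dmid, cand)][1]
    }
    new_class <- comp_class[cand[1]]
    merges[[length(merges) + 1L]] <-
      data.frame(from_class = names(SUBVOL_CLASSES)[comp_class[target]],
                 voxels = cnt[target],
                 to_class = names(SUBVOL_CLASSES)[new_class])
    cls[tv] <- new_class
  }
  part$class_map <- mask3d(cls, part$spacing, part$class_map$origin,
                           label_set = 0:3)
  part$merges <- if (length(merges)) do.call(rbind, merges) else NULL
  part$components <- subvol_components(part)
  part
}

#' Measure sub-volume sizes
#'
#' Per-class volume in ml (`voxels * voxel volume / 1000`) and percentage of
#' the total tumor volume, in the layout of a planning report.
#'
#' @param part a `subvol_partition`, or a data frame / named vector of ml
#'   values per class (for re-computing a printed report).
#' @param spacing voxel spacing in mm (taken from `part` when available).
#' @param total_ml reference total volume for the percentages. Defaults to
#'   the sum of the class volumes; pass the union volume explicitly when the
#'   classes are margin-expanded planning volumes that overlap (overlapping
#'   margins make the class volumes sum to more than the union).
#' @return Object of class `subvol_report`: data frame with columns `class`,
#'   `ml`, `percent`, plus attribute `total_ml`. Percentages are reported to
#'   2 decimals by `print()`.
#' @export
measure_subvolumes <- function(part, spacing = NULL, total_ml = NULL) {
  if (inherits(part, "subvol_partition")) {
    if (is.null(spacing)) spacing <- part$spacing
    vx_ml <- prod(spacing) / 1000
    cls <- part$class_map$labels
    ml <- vapply(SUBVOL_CLASSES, function(cl) sum(cls == cl) * vx_ml, 0)
  } else {
    ml <- unlist(part)
    if (is.null(names(ml)) || !all(names(ml) %in% names(SUBVOL_CLASSES)))
      names(ml) <- names(SUBVOL_CLASSES)[seq_along(ml)]
  }
  total <- if (is.null(total_ml)) sum(ml) else total_ml
  if (total <= 0) stop("total volume must be positive")
  rep <- data.frame(class = names(ml), ml = as.numeric(ml),
                    percent = as.numeric(ml) / total * 100)
  attr(rep, "total_ml") <- total
  class(rep) <- c("subvol_report", "data.frame")
  rep
}

#' @export
print.subvol_report <- function(x, ...) {
  cat(sprintf("total tumor volume: %.2f ml\n", attr(x, "total_ml")))
  df <- data.frame(class = x$class, ml = sprintf("%.2f", x$ml),
                   percent = sprintf("%.2f", x$percent))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.subvol_partition <- function(x, ...) {
  cat("metabolic sub-volume partition (SUVmax ref:",
      sprintf("%.3f", x$suv_max_ref), ")\n")
  print(measure_subvolumes(x))
  if (!is.null(x$merges))
    cat(nrow(x$merges), "small component(s) merged\n")
  invisible(x)
}

#' Expand a structure by a physical margin
#'
#' Morphological dilation with a spacing-aware ellipsoidal structuring element
#' of physical radius `margin_mm` (a voxel joins the expansion when its centre
#' lies within `margin_mm` of a foreground voxel centre). Used to grow tumor
#' sub-volumes into planning target volumes.
#'
#' @param mask a [mask3d()] (binary foreground = labels != 0).
#' @param margin_mm margin radius in mm (>= 0; 0 is the identity).
#' @return A [mask3d()] superset of the input, clipped to the grid.
#' @export
expand_margin <- function(mask, margin_mm = 10) {
  if (margin_mm < 0) stop("`margin_mm` must be >= 0")
  fg <- mask_fg(mask)
  off <- ball_offsets(margin_mm, mask$spacing)
  out <- dilate_mask(fg, off)
  mask3d(out, mask$spacing, mask$origin)
}

#' Planning target volumes for the three metabolic sub-volumes
#'
#' Applies a margin to each class of a partition. Because margins of
#' different classes may overlap, both variants are returned: `overlapping`
#' (each class dilated independently) and `exclusive` (overlap resolved with
#' priority high > mod > low).
#'
#' @param part a `subvol_partition`.
#' @param margin_mm margin radius in mm. Default 10.
#' @return List with `overlapping` (list of [mask3d()] per class) and
#'   `exclusive` (one [mask3d()] with labels 1/2/3).
#' @export
subvolume_ptvs <- function(part, margin_mm = 10) {
  cls <- part$class_map$labels
  sp <- part$spacing
  org <- part$class_map$origin
  over <- lapply(SUBVOL_CLASSES, function(cl) {
    expand_margin(mask3d(cls == cl, sp, org), margin_mm)
  })
  names(over) <- names(SUBVOL_CLASSES)
  excl <- array(0L, dim = dim(cls))
  for (nm in c("low", "mod", "high")) # later assignments win: high on top
    excl[over[[nm]]$labels != 0L] <- SUBVOL_CLASSES[[nm]]
  list(overlapping = over,
       exclusive = mask3d(excl, sp, org, label_set = 0:3))
}
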