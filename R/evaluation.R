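# Segmentation-accuracy metrics (Dice similarity coefficient, Hausdorff
# distance in mm), dose-volume-histogram metrics and heterogeneity indexes
# for treatment-plan comparison, and the paired statistics used to compare
# plans across patients.

#' Dice similarity coefficient
#'
#' `DSC(A, B) = 2|A intersect B| / (|A| + |B|)`; 1 for identical non-empty
#' masks, 0 for disjoint masks, and defined as 1 when both are empty.
#'
#' @param a,b [mask3d()] objects or logical arrays on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  fa <- mask_fg(a); fb <- mask_fg(b)
  if (!identical(dim(fa), dim(fb))) stop("masks are not on the same grid")
  na <- sum(fa); nb <- sum(fb)
  if (na + nb == 0L) return(1)
  2 * sum(fa & fb) / (na + nb)
}

#' Surface voxels of a mask, in physical coordinates
#'
#' Foreground voxels with at least one background face-neighbour (the volume
#' border counts as background), mapped to voxel-centre positions in mm.
#'
#' @param mask a [mask3d()] or logical array.
#' @param spacing,origin grid geometry (taken from the mask when available).
#' @return `n x 3` matrix of surface point coordinates (mm).
#' @export
surface_voxels <- function(mask, spacing = NULL, origin = NULL) {
  if (is_mask(mask)) {
    if (is.null(spacing)) spacing <- mask$spacing
    if (is.null(origin)) origin <- mask$origin
  } else {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  fg <- mask_fg(mask)
  if (!any(fg)) stop("mask is empty")
  surf <- fg & !erode_mask(fg, cross_offsets())
  idx <- which(surf, arr.ind = TRUE)
  voxel_mm(idx, spacing, origin)
}

#' Hausdorff distance between two masks (mm)
#'
#' The maximum over both directions of the sup-inf Euclidean distance between
#' the two surface point sets, with distances computed in mm using the voxel
#' spacing. 0 if and only if the masks are identical.
#'
#' @param a,b non-empty [mask3d()] objects or logical arrays on the same grid.
#' @param spacing voxel spacing (mm), taken from `a` when it is a [mask3d()].
#' @return Scalar distance in mm.
#' @export
hausdorff <- function(a, b, spacing = NULL) {
  fa <- mask_fg(a); fb <- mask_fg(b)
  if (!identical(dim(fa), dim(fb))) stop("masks are not on the same grid")
  if (!any(fa) || !any(fb)) stop("Hausdorff distance needs non-empty masks")
  sa <- surface_voxels(a, spacing = spacing)
  sb <- surface_voxels(b, spacing = spacing)
  max(.hausdorff_directed_cpp(sa, sb), .hausdorff_directed_cpp(sb, sa))
}

#' Two-tailed paired t-test
#'
#' For paired measurements the statistic is
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = y - x` and the sample standard
#' deviation (n - 1 denominator); the p-value is the two-tailed Student-t
#' tail probability with `n - 1` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return List with `t`, `p`, `df` and `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) stop("at least 2 pairs are required")
  d <- y - x
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences; the paired t-test is degenerate")
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1, mean_diff = mean(d))
}

#' Cumulative dose-volume histogram
#'
#' For each dose bin, the fraction of the structure volume receiving at least
#' that dose. The curve starts at 1 for 0 Gy, is non-increasing, and reaches
#' 0 above the maximum structure dose.
#'
#' @param dose an [suv_volume()]-like object or 3-D array of dose in Gy.
#' @param structure a [mask3d()] or logical array on the same grid.
#' @param bin_width_gy bin width in Gy. Default 0.1.
#' @return Object of class `dvh_curve`: `dose_gy` (ascending bin edges) and
#'   `volume_fraction`.
#' @export
compute_dvh <- function(dose, structure, bin_width_gy = 0.1) {
  if (bin_width_gy <= 0) stop("`bin_width_gy` must be positive")
  darr <- if (inherits(dose, "suv_volume")) dose$data else dose
  fg <- mask_fg(structure, dim(darr))
  if (!any(fg)) stop("structure mask is empty")
  ds <- sort(as.numeric(darr[fg]))
  n <- length(ds)
  top <- (floor(max(ds) / bin_width_gy) + 1L) * bin_width_gy
  bins <- seq(0, top, by = bin_width_gy)
  nless <- findInterval(bins - 1e-9, ds)
  out <- list(dose_gy = bins, volume_fraction = 1 - nless / n)
  class(out) <- "dvh_curve"
  out
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("cumulative DVH: %d bins, 0-%.1f Gy\n",
              length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ...) {
  graphics::plot(x$dose_gy, x$volume_fraction * 100, type = "l",
                 xlab = "dose (Gy)", ylab = "volume (%)",
                 ylim = c(0, 100), ...)
  invisible(x)
}

# dose received by at least x% of the structure volume (near-max for small x),
# from the sorted sample with linear interpolation between order statistics
dose_at_volume <- function(ds_desc, x_pct) {
  n <- length(ds_desc)
  pos <- x_pct / 100 * n
  if (pos <= 1) return(ds_desc[1])
  if (pos >= n) return(ds_desc[n])
  k <- floor(pos)
  frac <- pos - k
  ds_desc[k] * (1 - frac) + ds_desc[k + 1] * frac
}

#' Dose metrics and heterogeneity indexes for a structure
#'
#' Computes `D2` / `D98` (dose received by at least 2 % / 98 % of the
#' structure volume: the near-maximal and near-minimal dose), mean dose,
#' `Vx` (% of structure volume receiving at least x Gy) for each requested
#' threshold, and two heterogeneity indexes: `HI_RTOG = Imax / RI` and
#' `HI_D2,D98 = (D2 - D98) / Dp x 100`. A plan complies with protocol when
#' `HI_RTOG <= 2`.
#'
#' @param dose dose grid (array or [suv_volume()]-like, Gy).
#' @param structure a [mask3d()] or logical array.
#' @param dp prescribed dose (Gy, > 0).
#' @param ri reference isodose (Gy, > 0). Default `dp`.
#' @param vx_thresholds numeric vector of Vx thresholds in Gy.
#' @param imax maximum isodose in the target; default the maximum structure
#'   dose.
#' @param bin_width_gy DVH bin width for the attached curve. Default 0.1.
#' @return Object of class `plan_metrics` with fields `d2`, `d98`, `dmean`,
#'   `vx` (named %, one per threshold), `hi_rtog`, `hi_d2d98`, `imax`, `ri`,
#'   `dp`, `compliant`, `dvh`.
#' @export
dose_metrics <- function(dose, structure, dp, ri = dp,
                         vx_thresholds = numeric(), imax = NULL,
                         bin_width_gy = 0.1) {
  if (dp <= 0) stop("`dp` must be positive")
  if (ri <= 0) stop("`ri` must be positive")
  darr <- if (inherits(dose, "suv_volume")) dose$data else dose
  fg <- mask_fg(structure, dim(darr))
  if (!any(fg)) stop("structure mask is empty")
  ds <- sort(as.numeric(darr[fg]), decreasing = TRUE)
  d2 <- dose_at_volume(ds, 2)
  d98 <- dose_at_volume(ds, 98)
  if (is.null(imax)) imax <- ds[1]
  vx <- vapply(vx_thresholds, function(x) mean(ds >= x) * 100, 0)
  names(vx) <- if (length(vx_thresholds)) paste0("V", vx_thresholds)
               else character()
  out <- list(d2 = d2, d98 = d98, dmean = mean(ds),
              vx = vx, imax = imax, ri = ri, dp = dp,
              hi_rtog = imax / ri,
              hi_d2d98 = (d2 - d98) / dp * 100,
              compliant = (imax / ri) <= 2,
              dvh = compute_dvh(darr, fg, bin_width_gy))
  class(out) <- "plan_metrics"
  out
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("D2 %.2f Gy | D98 %.2f Gy | Dmean %.2f Gy\n",
              x$d2, x$d98, x$dmean))
  cat(sprintf("HI_RTOG %.2f (%s) | HI_D2,D98 %.2f\n", x$hi_rtog,
              if (x$compliant) "complies" else "exceeds protocol", x$hi_d2d98))
  if (length(x$vx))
    cat(paste(sprintf("%s %.2f%%", names(x$vx), x$vx), collapse = " | "), "\n")
  invisible(x)
}

#' Segmentation accuracy of an automated mask against a reference
#'
#' Convenience wrapper returning both the Dice coefficient and the Hausdorff
#' distance.
#'
#' @param auto,manual [mask3d()] objects on the same grid.
#' @return List of class `seg_eval` with `dsc` and `hd_mm`.
#' @export
evaluate_segmentation <- function(auto, manual) {
  out <- list(dsc = dice(auto, manual), hd_mm = hausdorff(auto, manual))
  class(out) <- "seg_eval"
  out
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("DSC %.3f | HD %.2f mm\n", x$dsc, x$hd_mm))
  invisible(x)
}
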