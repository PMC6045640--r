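#' Control parameters for the segmentation pipeline
#'
#' Collects every tunable parameter with validated defaults.
#'
#' @param level_fraction salient-region threshold as a fraction of the MIP
#'   plane maximum (stage 1). Default 0.30, below the 15--50 % SUVmax band in
#'   which tumor boundaries are expected, so the whole tumor projection stays
#'   salient.
#' @param neighbour_min_distance_mm minimum distance (mm) between the seed
#'   peak and a neighbouring peak for the scene to count as attached.
#'   Default 15.
#' @param neighbour_min_height_frac minimum neighbour-peak height as a
#'   fraction of the seed-peak height. Default 0.5; suppresses spurious noise
#'   maxima.
#' @param saddle_prominence_frac a neighbouring peak counts as a separate
#'   structure only when the saddle (the highest connecting pass) drops below
#'   this fraction of the lower peak. Default 0.85; shallower dips are
#'   internal heterogeneity (e.g. a necrotic core seen in projection) and are
#'   not separated.
#' @param projection_axes projection axes used in stage 1. Default `1:3`.
#' @param beta_magnitude `|beta|` of the joint affinity. Default 60. Only the
#'   sign of `beta` matters, so the magnitude does not change the result.
#' @param sigma Gaussian standard deviation (voxels) for the filtered
#'   gradient magnitude. Default 1.5.
#' @param box_radius half-width (voxels) of the mean-SUV box. Default 1.
#' @param tau affinity threshold of the stopping rule. Default 1 (freeze
#'   where the smoothed gradient magnitude stops rising inward).
#' @param neighbour_connectivity front-propagation adjacency, 6 or 26.
#'   Default 6.
#' @param regularize apply the one-voxel opening / component / hole-filling
#'   regularization after carving. Default `TRUE`.
#' @param merge_min_voxels minimum sub-volume component size (voxels); smaller
#'   components are merged into their nearest sub-volume. Default 25
#'   (a 5 x 5 x 1 planning-grid cell).
#' @param margin_mm PTV margin radius in mm. Default 10.
#' @param dvh_bin_gy DVH bin width in Gy. Default 0.1.
#' @param rng_seed optional integer seed for stochastic components.
#' @return A validated list of class `mtv_control`.
#' @export
mtv_control <- function(level_fraction = 0.30,
                        neighbour_min_distance_mm = 15,
                        neighbour_min_height_frac = 0.5,
                        saddle_prominence_frac = 0.85,
                        projection_axes = 1:3,
                        beta_magnitude = 60,
                        sigma = 1.5,
                        box_radius = 1L,
                        tau = 1,
                        neighbour_connectivity = 6L,
                        regularize = TRUE,
                        merge_min_voxels = 25L,
                        margin_mm = 10,
                        dvh_bin_gy = 0.1,
                        rng_seed = NULL) {
  ctl <- list(level_fraction = level_fraction,
              neighbour_min_distance_mm = neighbour_min_distance_mm,
              neighbour_min_height_frac = neighbour_min_height_frac,
              saddle_prominence_frac = saddle_prominence_frac,
              projection_axes = as.integer(projection_axes),
              beta_magnitude = beta_magnitude,
              sigma = sigma,
              box_radius = as.integer(box_radius),
              tau = tau,
              neighbour_connectivity = as.integer(neighbour_connectivity),
              regularize = isTRUE(regularize),
              merge_min_voxels = as.integer(merge_min_voxels),
              margin_mm = margin_mm,
              dvh_bin_gy = dvh_bin_gy,
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  validate_control(ctl)
  class(ctl) <- "mtv_control"
  ctl
}

validate_control <- function(ctl) {
  stopifnot(ctl$level_fraction > 0, ctl$level_fraction < 1,
            ctl$neighbour_min_distance_mm >= 0,
            ctl$neighbour_min_height_frac >= 0,
            ctl$neighbour_min_height_frac <= 1,
            ctl$saddle_prominence_frac > 0, ctl$saddle_prominence_frac <= 1,
            all(ctl$projection_axes %in% 1:3),
            length(ctl$projection_axes) >= 1,
            ctl$beta_magnitude > 0,
            ctl$sigma > 0,
            ctl$box_radius >= 1,
            ctl$tau > 0,
            ctl$neighbour_connectivity %in% c(6L, 26L),
            ctl$merge_min_voxels >= 1,
            ctl$margin_mm >= 0,
            ctl$dvh_bin_gy > 0)
  invisible(ctl)
}

#' Build a control object from a YAML configuration file
#'
#' Unknown keys are rejected; supplied keys override the defaults.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file.
#' @return A [mtv_control()].
#' @export
read_control <- function(path, ...) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  known <- names(formals(mtv_control))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(mtv_control, cfg)
}

#' @export
print.mtv_seg <- function(x, ...) {
  vx <- prod(x$tumor$spacing) / 1000
  n <- sum(x$tumor$labels != 0L)
  cat("PET tumor segmentation (MIP separation + hill-climbing shrink)\n")
  cat(sprintf("  tumor volume : %d voxels = %.2f ml\n", n, n * vx))
  cat(sprintf("  SUVmax       : %.3f\n", x$suv_max))
  cat(sprintf("  seed voxel   : (%d, %d, %d)\n", x$seed[1], x$seed[2], x$seed[3]))
  cat(sprintf("  masking surface: %d voxels\n", sum(x$ms$labels != 0L)))
  invisible(x)
}

#' @export
summary.mtv_seg <- function(object, ...) {
  b <- object$boundary_suv / object$suv_max * 100
  s <- list(tumor_voxels = sum(object$tumor$labels != 0L),
            tumor_ml = sum(object$tumor$labels != 0L) *
              prod(object$tumor$spacing) / 1000,
            suv_max = object$suv_max,
            boundary_suv_pct = stats::quantile(b, c(0.05, 0.5, 0.95)),
            timings = object$timings)
  class(s) <- "summary.mtv_seg"
  s
}

#' @export
print.summary.mtv_seg <- function(x, ...) {
  cat(sprintf("tumor: %d voxels (%.2f ml), SUVmax %.3f\n",
              x$tumor_voxels, x$tumor_ml, x$suv_max))
  cat(sprintf("boundary SUV [5%%, 50%%, 95%%]: %.1f / %.1f / %.1f %% of SUVmax\n",
              x$boundary_suv_pct[1], x$boundary_suv_pct[2], x$boundary_suv_pct[3]))
  cat(sprintf("timings: stage 1 %.2fs, stage 2 %.2fs\n",
              x$timings["stage1"], x$timings["stage2"]))
  invisible(x)
}

#' Plot a segmentation result
#'
#' Shows the axial slice through the seed with the tumor contour overlay.
#'
#' @param x an `mtv_seg` object.
#' @param slice axial slice index (default: the seed slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.mtv_seg <- function(x, slice = NULL, ...) {
  k <- if (is.null(slice)) x$seed[3] else as.integer(slice)
  f <- x$vol$data[, , k]
  graphics::image(seq_len(nrow(f)) * x$vol$spacing[1],
                  seq_len(ncol(f)) * x$vol$spacing[2], f,
                  col = grDevices::gray.colors(128, 0, 1), asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("axial slice %d", k), ...)
  m <- x$tumor$labels[, , k]
  if (any(m != 0))
    graphics::contour(seq_len(nrow(f)) * x$vol$spacing[1],
                      seq_len(ncol(f)) * x$vol$spacing[2], m,
                      levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "red", lwd = 2)
  invisible(x)
}
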