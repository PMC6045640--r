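# Internal voxel-grid utilities: separable filters, connected components,
# morphology. These back several user-facing operations.

gauss_kernel <- function(sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  x <- seq(-hw, hw)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing, sigma in voxels (scalar or per-axis),
# replicate padding so flat fields stay flat at the border
gauss_smooth <- function(arr, sigma) {
  dm <- as.integer(dim(arr))
  sigma <- rep_len(sigma, 3L)
  out <- as.double(arr)
  for (ax in 1:3) {
    if (sigma[ax] <= 0 || dm[ax] == 1L) next
    out <- .convolve_axis_cpp(out, dm, ax, gauss_kernel(sigma[ax]), 1L)
  }
  array(out, dim = dm)
}

# box mean over the (2r+1)^3 neighbourhood clipped to the volume bounds:
# zero-padded sum convolution divided by the in-bounds voxel count
box_mean <- function(arr, r) {
  dm <- as.integer(dim(arr))
  kern <- rep(1, 2L * r + 1L)
  s <- as.double(arr)
  cnt <- rep(1, length(s))
  for (ax in 1:3) {
    s <- .convolve_axis_cpp(s, dm, ax, kern, 0L)
    cnt <- .convolve_axis_cpp(cnt, dm, ax, kern, 0L)
  }
  array(s / cnt, dim = dm)
}

# connected-component labelling of a logical array (2-D matrices are treated
# as one-slice 3-D grids; connectivity 26 is then 8-connectivity in-plane)
label_components <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  if (length(dm) == 2L) dm <- c(dm, 1L)
  lab <- .cc_label_cpp(as.logical(mask), as.integer(dm), as.integer(connectivity))
  array(lab, dim = dim(mask))
}

# integer offsets of voxel centres within a physical radius (mm), inclusive
ball_offsets <- function(radius_mm, spacing) {
  nr <- floor(radius_mm / spacing)
  if (radius_mm <= 0) return(matrix(0L, nrow = 1, ncol = 3))
  g <- expand.grid(di = -nr[1]:nr[1], dj = -nr[2]:nr[2], dk = -nr[3]:nr[3])
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  m <- as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

dilate_mask <- function(mask, offsets) {
  dm <- as.integer(dim(mask))
  array(.dilate_offsets_cpp(as.logical(mask), dm, offsets), dim = dim(mask))
}

erode_mask <- function(mask, offsets) {
  dm <- as.integer(dim(mask))
  array(.erode_offsets_cpp(as.logical(mask), dm, offsets), dim = dim(mask))
}

cross_offsets <- function() {
  m <- rbind(c(0L, 0L, 0L),
             c(1L, 0L, 0L), c(-1L, 0L, 0L),
             c(0L, 1L, 0L), c(0L, -1L, 0L),
             c(0L, 0L, 1L), c(0L, 0L, -1L))
  storage.mode(m) <- "integer"
  m
}

# fill cavities: background components (6-connectivity) that do not touch the
# volume border are converted to foreground
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 6L)
  dm <- dim(mask)
  border <- unique(c(lab[c(1, dm[1]), , ], lab[, c(1, dm[2]), ], lab[, , c(1, dm[3])]))
  border <- setdiff(border, 0L)
  mask | (bg & !(lab %in% border))
}

# seed's connected component of a logical mask
seed_component <- function(mask, seed, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  sl <- lab[seed[1], seed[2], seed[3]]
  if (sl == 0L) stop("seed is not inside the mask")
  lab == sl
}
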