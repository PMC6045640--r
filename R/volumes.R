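#' @useDynLib mtvseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' SUV volume constructor
#'
#' A `suv_volume` holds a 3-D grid of standardized uptake values (SUV,
#' dimensionless) together with its physical geometry: per-axis voxel size in
#' mm and a physical origin (the position of the centre of voxel `(1,1,1)`).
#' Arrays use R's native `(x, y, z)` dimension order; a voxel index `(i, j, k)`
#' (1-based) sits at physical position `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param data 3-D numeric array of SUV; all values must be finite and >= 0.
#' @param spacing numeric length-3, voxel size in mm along (x, y, z); all > 0.
#' @param origin numeric length-3, physical offset in mm. Default `c(0,0,0)`.
#' @return An object of class `suv_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
suv_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all array dimensions must be >= 1")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("SUV values must all be finite")
  if (any(data < 0)) stop("SUV values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' Binary or label mask on a voxel grid
#'
#' A `mask3d` is an integer label field on the same grid as an associated
#' [suv_volume()]. Label 0 is background; 1 is foreground (tumor); partitions
#' may use further class codes. The declared `label_set` bounds the labels the
#' mask may carry.
#'
#' @param labels 3-D integer (or logical) array.
#' @param spacing voxel size in mm along (x, y, z).
#' @param origin physical offset in mm.
#' @param label_set integer vector of permitted labels (must include every
#'   label present).
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(labels, spacing, origin = c(0, 0, 0),
                   label_set = c(0L, 1L)) {
  if (is.logical(labels)) {
    dm <- dim(labels)
    labels <- array(as.integer(labels), dim = dm)
  }
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA")
  label_set <- sort(unique(as.integer(label_set)))
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% label_set))
    stop("mask contains labels outside its declared label set: ",
         paste(setdiff(present, label_set), collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin), label_set = label_set),
            class = "mask3d")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("SUV volume:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(format(x$spacing, digits = 4), collapse = " x "),
      "mm\n  SUV range:", format(min(x$data), digits = 4), "-",
      format(max(x$data), digits = 4), "\n")
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat("3-D mask:", paste(dim(x$labels), collapse = " x "),
      "voxels,", paste(format(x$spacing, digits = 4), collapse = " x "),
      "mm\n  foreground voxels:", sum(x$labels != 0L),
      " labels: {", paste(x$label_set, collapse = ", "), "}\n")
  invisible(x)
}

#' Seed voxel
#'
#' A user-supplied voxel index (1-based, `(i, j, k)` along x/y/z) marking the
#' target tumor. Must lie strictly inside the volume and on a voxel with
#' positive SUV.
#'
#' @param index integer length-3 voxel index.
#' @param vol optional [suv_volume()] to validate against.
#' @return Integer vector of class `seed_voxel`.
#' @export
seed_voxel <- function(index, vol = NULL) {
  index <- as.integer(round(index))
  if (length(index) != 3L || anyNA(index)) stop("seed index must be 3 integers")
  if (!is.null(vol)) {
    dm <- dim(vol$data)
    if (any(index < 1L) || any(index > dm))
      stop("seed lies outside the volume bounds")
    if (vol$data[index[1], index[2], index[3]] <= 0)
      stop("SUV at the seed must be positive")
  }
  structure(index, class = "seed_voxel")
}

is_mask <- function(x) inherits(x, "mask3d")

#' Read a volume or mask from disk
#'
#' Reads a NIfTI-1 image (`.nii` / `.nii.gz`) into an [suv_volume()] or
#' [mask3d()]. Spacing is taken from the header `pixdim`; the origin from the
#' stored transform. Images with trailing singleton dimensions (e.g. a 4th
#' axis of extent 1) are squeezed to 3-D with a warning.
#'
#' @param path file path.
#' @param format only `"nifti"` is supported. (DICOM series input is not
#'   available in this build; convert series to NIfTI first.)
#' @param as `"suv"` for an SUV volume or `"mask"` for an integer label mask.
#' @return An [suv_volume()] or [mask3d()].
#' @export
load_volume <- function(path, format = c("nifti", "dicom_series"),
                        as = c("suv", "mask")) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (format == "dicom_series")
    stop("DICOM series reading is not supported in this build; ",
         "convert the series to NIfTI first")
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dm <- dim(arr)
  if (length(dm) > 3L) {
    if (all(dm[-(1:3)] == 1L)) {
      warning("squeezing ", length(dm), "-D image with singleton axes to 3-D")
      arr <- array(arr, dim = dm[1:3])
    } else {
      stop("'", path, "' is not a 3-D image (dim = ",
           paste(dm, collapse = " x "), ")")
    }
  }
  if (length(dim(arr)) < 3L) stop("'", path, "' is not a 3-D image")
  arr <- array(as.numeric(arr), dim = dim(arr)) # drop image attributes
  spacing <- abs(RNifti::pixdim(img))[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  if (as == "mask") {
    arr <- round(arr)
    storage.mode(arr) <- "integer"
    mask3d(arr, spacing, origin, label_set = sort(unique(as.vector(arr))))
  } else {
    suv_volume(arr, spacing, origin)
  }
}

#' Write a volume or mask to disk as NIfTI
#'
#' Spacing and origin are stored in the header (sform). Masks are stored with
#' an integer datatype so labels survive a round trip exactly.
#'
#' @param vol an [suv_volume()] or [mask3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param format only `"nifti"`.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path, format = "nifti") {
  if (!identical(format, "nifti")) stop("only NIfTI output is supported")
  is_m <- is_mask(vol)
  arr <- if (is_m) vol$labels else vol$data
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  dtype <- if (is_m) "int32" else "double"
  ok <- try(RNifti::writeNifti(img, path, datatype = dtype), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write '", path, "': ", attr(ok, "condition")$message)
  invisible(path)
}

#' Resample a volume to a new voxel spacing
#'
#' Resamples onto a grid with the requested spacing covering the same physical
#' extent (to within one target voxel). SUV volumes may use trilinear or
#' nearest-neighbour interpolation; masks must use nearest-neighbour so that no
#' new labels are invented. Negative values arising from interpolation are
#' clipped to 0 (SUV is physically non-negative).
#'
#' @param vol an [suv_volume()] or [mask3d()].
#' @param target_spacing numeric length-3 target voxel size in mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A resampled object of the same class as `vol`.
#' @export
resample_to_grid <- function(vol, target_spacing,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_m <- is_mask(vol)
  if (is_m && interpolation == "linear")
    stop("masks must be resampled with nearest-neighbour interpolation")
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive numbers (mm)")
  arr <- if (is_m) vol$labels else vol$data
  dm <- dim(arr)
  sp <- vol$spacing
  out_dim <- pmax(1L, as.integer(round(dm * sp / target_spacing)))
  # voxel-centre alignment: output index u maps to source index
  # x = u * (target / source); both grids share the origin at voxel centre 1
  src_pos <- function(ud, ax) (ud - 1) * target_spacing[ax] / sp[ax] + 1
  gx <- src_pos(seq_len(out_dim[1]), 1)
  gy <- src_pos(seq_len(out_dim[2]), 2)
  gz <- src_pos(seq_len(out_dim[3]), 3)
  if (interpolation == "nearest") {
    ix <- pmin(pmax(round(gx), 1L), dm[1])
    iy <- pmin(pmax(round(gy), 1L), dm[2])
    iz <- pmin(pmax(round(gz), 1L), dm[3])
    out <- arr[ix, iy, iz, drop = FALSE]
  } else {
    x0 <- pmin(pmax(floor(gx), 1L), dm[1]); x1 <- pmin(x0 + 1L, dm[1])
    y0 <- pmin(pmax(floor(gy), 1L), dm[2]); y1 <- pmin(y0 + 1L, dm[2])
    z0 <- pmin(pmax(floor(gz), 1L), dm[3]); z1 <- pmin(z0 + 1L, dm[3])
    fx <- pmin(pmax(gx - x0, 0), 1); fy <- pmin(pmax(gy - y0, 0), 1)
    fz <- pmin(pmax(gz - z0, 0), 1)
    FX <- array(fx, dim = out_dim)
    FY <- array(rep(fy, each = out_dim[1]), dim = out_dim)
    FZ <- array(rep(fz, each = out_dim[1] * out_dim[2]), dim = out_dim)
    out <- arr[x0, y0, z0, drop = FALSE] * (1 - FX) * (1 - FY) * (1 - FZ) +
           arr[x1, y0, z0, drop = FALSE] * FX       * (1 - FY) * (1 - FZ) +
           arr[x0, y1, z0, drop = FALSE] * (1 - FX) * FY       * (1 - FZ) +
           arr[x1, y1, z0, drop = FALSE] * FX       * FY       * (1 - FZ) +
           arr[x0, y0, z1, drop = FALSE] * (1 - FX) * (1 - FY) * FZ +
           arr[x1, y0, z1, drop = FALSE] * FX       * (1 - FY) * FZ +
           arr[x0, y1, z1, drop = FALSE] * (1 - FX) * FY       * FZ +
           arr[x1, y1, z1, drop = FALSE] * FX       * FY       * FZ
    out[out < 0] <- 0
  }
  if (is_m) {
    storage.mode(out) <- "integer"
    mask3d(out, target_spacing, vol$origin, label_set = vol$label_set)
  } else {
    suv_volume(out, target_spacing, vol$origin)
  }
}

#' Maximum SUV within a mask
#'
#' The normalizer for all fractional-uptake thresholds: SUVmax over the
#' foreground voxels of `mask`.
#'
#' @param vol an [suv_volume()].
#' @param mask a [mask3d()] (foreground = labels != 0) or logical array.
#' @return Scalar maximum SUV.
#' @export
suv_max_in <- function(vol, mask) {
  fg <- mask_fg(mask, dim(vol$data))
  if (!any(fg)) stop("mask is empty")
  max(vol$data[fg])
}

# coerce a mask3d / logical / integer array to a logical foreground array
mask_fg <- function(mask, dm = NULL) {
  fg <- if (is_mask(mask)) mask$labels != 0L else mask != 0
  if (!is.null(dm) && !identical(dim(fg), as.integer(dm)))
    stop("mask grid does not match the volume grid")
  fg
}

# physical coordinates (mm) of the voxel centres of index matrix idx (n x 3)
voxel_mm <- function(idx, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}
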