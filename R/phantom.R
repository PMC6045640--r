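# Synthetic PET phantoms with analytic ground truth: a heterogeneous-uptake
# tumor (hot rim, moderate shell, low-uptake necrotic interior), an optional
# adjacent high-uptake organ ("heart"/mediastinum), low-uptake lung
# background, a point-spread blur, and additive Gaussian noise. Also builds
# synthetic dose grids for plan-evaluation testing.

#' Parametric description of a synthetic PET scene
#'
#' Geometry is specified in mm; memberships are analytic ellipsoids so that
#' ground-truth masks are exactly recoverable. Uptake inside the tumor varies
#' radially: a hot rim at `rim_suv` (the scene SUVmax) outside `rim_start`
#' of the ellipsoidal radius, a moderate shell at `shell_frac * rim_suv`, and
#' a low-uptake necrotic core at `core_frac * rim_suv` inside `core_radii_mm`.
#' An optional organ ellipsoid with high uptake can be placed against the
#' tumor (small `organ_gap_mm`) to emulate a tumor abutting the myocardium.
#'
#' @param grid_shape integer length-3 grid dimensions. Default `c(96,96,96)`.
#' @param spacing voxel size mm. Default 2 mm isotropic (a near-isotropic
#'   working grid representative of PET up-sampled toward CT resolution).
#' @param tumor_center_mm tumor centre (default: grid centre).
#' @param tumor_radii_mm ellipsoid semi-axes in mm. Default `c(20, 18, 16)`.
#' @param rim_suv SUV of the hot rim (scene SUVmax). Default 10.
#' @param shell_frac moderate-shell uptake as a fraction of `rim_suv`.
#'   Default 0.6.
#' @param core_frac necrotic-core uptake fraction. Default 0.08.
#' @param core_radii_mm necrotic core semi-axes. Default `0.45 *
#'   tumor_radii_mm`.
#' @param rim_start fractional ellipsoidal radius where the rim begins.
#'   Default 0.7.
#' @param taper_mm width in mm of the outward taper of the rim toward the
#'   boundary. Default 4 (a partial-volume length scale set by the scanner
#'   point-spread, not by tumor size).
#' @param edge_frac uptake at the pathological boundary (fractional radius 1)
#'   as a fraction of the rim peak. Default 0.5: the viable rim peaks inside
#'   the boundary and partial-volume tapers outward, so boundary-adjacent
#'   voxels sit near half the peak -- the configuration under which clinical
#'   tumor edges are observed at a quarter to a half of SUVmax.
#' @param organ logical: include the adjacent high-uptake organ.
#' @param organ_radii_mm organ semi-axes. Default `c(25, 22, 22)`.
#' @param organ_peak_frac organ uptake as a fraction of `rim_suv`.
#'   Default 0.9.
#' @param organ_gap_mm surface-to-surface distance along +x between tumor and
#'   organ; `<= 0` means overlapping. The default 1.5 mm is a sub-voxel
#'   interface: after the point-spread blur the two structures fuse into a
#'   single salient component (the attached case) while a faint uptake valley
#'   persists at the interface -- the saddle the separation mechanism
#'   exploits. With a genuine overlap no image evidence separates the
#'   structures at all.
#' @param background_suv lung background SUV. Default 0.5.
#' @param noise_sd_frac additive Gaussian noise SD as a fraction of
#'   `rim_suv`. Default 0 (noise-free).
#' @param psf_sigma_vox point-spread blur SD in voxels (per axis).
#'   Default 1.
#' @param lobulation_amp amplitude of a low-order angular modulation of the
#'   tumor radius (0 = smooth ellipsoid), emulating irregular margins.
#' @param rng_seed integer RNG seed; a fixed seed reproduces the scene
#'   bit-for-bit.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing = c(2, 2, 2),
                         tumor_center_mm = NULL,
                         tumor_radii_mm = c(20, 18, 16),
                         rim_suv = 10,
                         shell_frac = 0.6,
                         core_frac = 0.08,
                         core_radii_mm = NULL,
                         rim_start = 0.7,
                         taper_mm = 4,
                         edge_frac = 0.5,
                         organ = FALSE,
                         organ_radii_mm = c(25, 22, 22),
                         organ_peak_frac = 0.9,
                         organ_gap_mm = 1.5,
                         background_suv = 0.5,
                         noise_sd_frac = 0,
                         psf_sigma_vox = 1,
                         lobulation_amp = 0,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (is.null(tumor_center_mm))
    tumor_center_mm <- (grid_shape - 1) / 2 * spacing
  if (is.null(core_radii_mm)) core_radii_mm <- 0.45 * tumor_radii_mm
  spec <- list(grid_shape = grid_shape, spacing = spacing,
               tumor_center_mm = as.numeric(tumor_center_mm),
               tumor_radii_mm = as.numeric(tumor_radii_mm),
               rim_suv = rim_suv, shell_frac = shell_frac,
               core_frac = core_frac,
               core_radii_mm = as.numeric(core_radii_mm),
               rim_start = rim_start,
               taper_mm = taper_mm,
               edge_frac = edge_frac,
               organ = isTRUE(organ),
               organ_radii_mm = as.numeric(organ_radii_mm),
               organ_peak_frac = organ_peak_frac,
               organ_gap_mm = organ_gap_mm,
               background_suv = background_suv,
               noise_sd_frac = noise_sd_frac,
               psf_sigma_vox = psf_sigma_vox,
               lobulation_amp = lobulation_amp,
               rng_seed = as.integer(rng_seed))
  stopifnot(all(spec$grid_shape >= 1L), all(spec$spacing > 0),
            all(spec$tumor_radii_mm > 0), all(spec$core_radii_mm > 0),
            spec$rim_suv > 0,
            spec$core_frac > 0, spec$core_frac < spec$shell_frac,
            spec$shell_frac < 1,
            spec$rim_start > 0, spec$rim_start < 1,
            spec$taper_mm >= 0,
            spec$edge_frac > 0, spec$edge_frac <= 1,
            spec$background_suv >= 0, spec$noise_sd_frac >= 0,
            spec$rim_suv > spec$background_suv)
  lo <- spec$tumor_center_mm - spec$tumor_radii_mm
  hi <- spec$tumor_center_mm + spec$tumor_radii_mm
  if (any(lo < 0) || any(hi > (grid_shape - 1) * spacing))
    stop("tumor extends outside the grid")
  class(spec) <- "phantom_spec"
  spec
}

# organ centre implied by the gap setting: offset along +x
organ_center <- function(spec) {
  c(spec$tumor_center_mm[1] + spec$tumor_radii_mm[1] +
      spec$organ_gap_mm + spec$organ_radii_mm[1],
    spec$tumor_center_mm[2], spec$tumor_center_mm[3])
}

# squared ellipsoidal radius field for a centre/radii pair, given coordinate
# vectors (mm) along each axis
ellipsoid_rho <- function(xs, ys, zs, center, radii) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  rx <- (xs - center[1]) / radii[1]
  ry <- (ys - center[2]) / radii[2]
  rz <- (zs - center[3]) / radii[3]
  a <- array(rx^2, dim = c(nx, ny, nz))
  a <- a + array(rep(ry^2, each = nx), dim = c(nx, ny, nz))
  a <- a + array(rep(rz^2, each = nx * ny), dim = c(nx, ny, nz))
  sqrt(a)
}

# low-order angular modulation factor for lobulated margins (deterministic,
# smooth, mean approximately 1)
lobulation_factor <- function(xs, ys, zs, center, amp) {
  if (amp == 0) return(1)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  dx <- array(xs - center[1], dim = c(nx, ny, nz))
  dy <- array(rep(ys - center[2], each = nx), dim = c(nx, ny, nz))
  dz <- array(rep(zs - center[3], each = nx * ny), dim = c(nx, ny, nz))
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- 1
  theta <- atan2(dy, dx)
  cosph <- dz / r
  1 + amp * sin(3 * theta) * (1 - cosph^2)
}

#' Generate a synthetic PET scene with ground truth
#'
#' Builds the piecewise-constant uptake template from the spec's analytic
#' geometry, blurs it with a Gaussian point-spread of `psf_sigma_vox` voxels,
#' adds Gaussian noise (clipped at zero), and returns the volume together
#' with the analytic truth masks and the seed (the tumor-centroid voxel).
#'
#' @param spec a [phantom_spec()].
#' @return List with `vol` ([suv_volume()]), `truth_tumor`, `truth_organ`,
#'   `organ_core` ([mask3d()]; empty masks when no organ), `seed`
#'   ([seed_voxel()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  dm <- spec$grid_shape
  sp <- spec$spacing
  xs <- (seq_len(dm[1]) - 1) * sp[1]
  ys <- (seq_len(dm[2]) - 1) * sp[2]
  zs <- (seq_len(dm[3]) - 1) * sp[3]
  lob <- lobulation_factor(xs, ys, zs, spec$tumor_center_mm,
                           spec$lobulation_amp)
  rho_t <- ellipsoid_rho(xs, ys, zs, spec$tumor_center_mm,
                         spec$tumor_radii_mm) / lob
  rho_c <- ellipsoid_rho(xs, ys, zs, spec$tumor_center_mm,
                         spec$core_radii_mm)
  truth_tumor <- rho_t <= 1
  core <- rho_c <= 1
  shell <- truth_tumor & !core & rho_t < spec$rim_start
  rim <- truth_tumor & !core & rho_t >= spec$rim_start
  template <- array(spec$background_suv, dim = dm)
  # rim plateau with an outward taper toward the boundary over taper_mm:
  # approximate distance to the (lobulated) surface along the ray from the
  # centre as (1 - rho) / rho * |x - c|
  rmag <- ellipsoid_rho(xs, ys, zs, spec$tumor_center_mm, c(1, 1, 1))
  dist_mm <- (1 - rho_t) * rmag / pmax(rho_t, 1e-6)
  tfac <- if (spec$taper_mm > 0)
    pmin(1, pmax(0, 1 - dist_mm / spec$taper_mm)) else 0
  rim_val <- spec$rim_suv * (1 - (1 - spec$edge_frac) * tfac)
  template[rim] <- rim_val[rim]
  template[shell] <- spec$shell_frac * spec$rim_suv
  template[core & truth_tumor] <- spec$core_frac * spec$rim_suv
  if (spec$organ) {
    oc <- organ_center(spec)
    rho_o <- ellipsoid_rho(xs, ys, zs, oc, spec$organ_radii_mm)
    truth_organ <- rho_o <= 1
    organ_core <- ellipsoid_rho(xs, ys, zs, oc, 0.6 * spec$organ_radii_mm) <= 1
    ov <- spec$organ_peak_frac * spec$rim_suv
    template[truth_organ & !truth_tumor] <-
      pmax(template[truth_organ & !truth_tumor], ov)
  } else {
    truth_organ <- array(FALSE, dim = dm)
    organ_core <- truth_organ
  }
  f <- gauss_smooth(template, spec$psf_sigma_vox)
  if (spec$noise_sd_frac > 0) {
    f <- withr::with_seed(spec$rng_seed, {
      f + stats::rnorm(length(f), sd = spec$noise_sd_frac * spec$rim_suv)
    })
    f[f < 0] <- 0
    f <- array(f, dim = dm)
  }
  idx <- which(truth_tumor, arr.ind = TRUE)
  seed_idx <- round(colMeans(idx))
  vol <- suv_volume(f, sp)
  list(vol = vol,
       truth_tumor = mask3d(truth_tumor, sp),
       truth_organ = mask3d(truth_organ, sp),
       organ_core = mask3d(organ_core, sp),
       seed = seed_voxel(seed_idx, vol),
       spec = spec)
}

#' Standard phantom suite
#'
#' A deterministic family of `n` scenes sweeping tumor size (semi-axes 10 to
#' 30 mm, with mild anisotropy) and necrotic-core uptake (5 to 20 % of
#' SUVmax). Every scene is necrotic; `attached = TRUE` places the high-uptake
#' organ against the tumor. Grids are sized per scene so that the tumor,
#' organ and a 30 mm background margin fit.
#'
#' @param n number of scenes. Default 20.
#' @param attached include the adjacent organ in every scene. Default `TRUE`.
#' @param noise_sd_frac noise level forwarded to each spec. Default 0.
#' @param rng_seed base RNG seed; scene `i` uses `rng_seed + i`.
#' @return List of [phantom_spec()] objects.
#' @export
standard_phantom_suite <- function(n = 20L, attached = TRUE,
                                   noise_sd_frac = 0, rng_seed = 100L) {
  n <- as.integer(n)
  radii <- seq(10, 30, length.out = n)
  cores <- seq(0.05, 0.20, length.out = n)
  # pair large radii with small cores and vice versa, deterministically
  cores <- cores[((seq_len(n) - 1L) * 7L) %% n + 1L]
  lapply(seq_len(n), function(i) {
    r <- radii[i]
    rad <- c(r, 0.9 * r, 0.8 * r)
    sp <- c(1.2, 1.2, 1.2)
    organ_r <- c(25, 22, 22)
    extent_x <- 2 * rad[1] + (if (attached) 2 * organ_r[1] else 0) + 60
    extent_yz <- 2 * max(rad[2], if (attached) organ_r[2] else 0) + 60
    shape <- as.integer(ceiling(c(extent_x, extent_yz, extent_yz) / sp))
    center <- c(rad[1] + 30, (shape[2] - 1) / 2 * sp[2],
                (shape[3] - 1) / 2 * sp[3])
    phantom_spec(grid_shape = shape, spacing = sp,
                 tumor_center_mm = center,
                 tumor_radii_mm = rad,
                 core_frac = cores[i],
                 core_radii_mm = 0.45 * rad,
                 organ = attached,
                 lobulation_amp = if (i %% 3 == 0) 0.08 else 0,
                 noise_sd_frac = noise_sd_frac,
                 rng_seed = rng_seed + i)
  })
}

#' Generate a synthetic dose grid for plan evaluation
#'
#' Builds a dose distribution from per-class planning volumes: inside each
#' class the class prescription (overlaps resolved with priority
#' high > mod > low), outside a Gaussian falloff of scale `falloff_mm` from
#' the nearest target (distance quantized in 2 mm shells), plus optional
#' low-amplitude Gaussian noise.
#'
#' @param ptv_classes named list of [mask3d()] per class (any subset of
#'   `low`, `mod`, `high`), all on one grid.
#' @param prescriptions named numeric vector of prescribed dose per class
#'   (Gy, > 0).
#' @param falloff_mm Gaussian falloff scale in mm. Default 5.
#' @param noise_sd dose noise SD in Gy. Default 0.
#' @param rng_seed RNG seed for the noise.
#' @return An [suv_volume()]-like container holding the dose grid (Gy).
#' @export
generate_dose_grid <- function(ptv_classes, prescriptions, falloff_mm = 5,
                               noise_sd = 0, rng_seed = 1L) {
  if (any(prescriptions <= 0)) stop("prescriptions must be positive")
  nms <- names(ptv_classes)
  if (is.null(nms) || !all(nms %in% c("low", "mod", "high")))
    stop("`ptv_classes` must be a named list with names in low/mod/high")
  ref <- ptv_classes[[1]]
  dm <- dim(ref$labels)
  sp <- ref$spacing
  dose <- array(0, dim = dm)
  # falloff from the union of targets, distance quantized in 2 mm shells
  union_fg <- Reduce(`|`, lapply(ptv_classes, mask_fg))
  pmax_presc <- max(prescriptions[nms])
  shell_step <- 2
  reach <- ceiling(5 * falloff_mm / shell_step)
  cur <- union_fg
  off <- ball_offsets(shell_step, sp)
  for (s in seq_len(reach)) {
    nxt <- dilate_mask(cur, off)
    ring <- nxt & !cur
    if (!any(ring)) break
    dose[ring] <- pmax_presc * exp(-(s * shell_step)^2 / (2 * falloff_mm^2))
    cur <- nxt
  }
  # class prescriptions, low first so high priority wins
  for (nm in intersect(c("low", "mod", "high"), nms))
    dose[mask_fg(ptv_classes[[nm]], dm)] <- prescriptions[[nm]]
  if (noise_sd > 0) {
    dose <- withr::with_seed(as.integer(rng_seed), {
      dose + stats::rnorm(length(dose), sd = noise_sd)
    })
    dose[dose < 0] <- 0
    dose <- array(dose, dim = dm)
  }
  suv_volume(dose, sp, ref$origin)
}
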