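---
title: "Delineating heterogeneous lung tumors on FDG-PET: the mtvseg model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating heterogeneous lung tumors on FDG-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtvseg)
```

## The delineation problem

The metabolic tumor volume on an FDG-PET scan is the basis both of target
definition in radiotherapy and of dose painting: prescribing a higher dose
to sub-volumes with higher metabolic activity. Fixed fractional-SUVmax
thresholds (40 % or 50 %, "RG40"/"RG50") fail in the two situations that
matter most clinically: when the tumor touches another high-uptake
structure (the threshold region leaks into the myocardium or mediastinum),
and when the tumor is heterogeneous, with a necrotic interior far below
the threshold (the low-uptake part of the tumor is cut out). `mtvseg`
implements a two-stage model that handles both, followed by a sub-volume
quantification designed for planning-system consumption.

## Stage 1: separation by maximum-intensity-projection masks

Each of the three axis-aligned maximum-intensity projections (MIPs)
reduces the scene to a 2-D image in which hot structures are salient
(`project_mip()`). The stage asks, per axis: does the component of the
thresholded MIP containing the (projected) seed also contain another
substantial peak? If so, the two structures are attached in this view and
must be split.

* **Salient level.** The MIP plane is thresholded at a fraction
  (`level_fraction`, default 0.30) of its maximum. The default sits below
  the 15–50 % SUVmax band in which tumor boundaries are clinically
  expected, so the whole tumor silhouette remains salient.
* **Peaks.** The seed's own peak is found by steepest ascent on a lightly
  smoothed copy of the plane; a neighbour peak is the highest regional
  maximum inside the same component that is at least
  `neighbour_min_distance_mm` (default 15 mm) away and at least
  `neighbour_min_height_frac` (default 0.5) of the seed peak. The height
  floor keeps noise maxima from being mistaken for organs.
* **Saddle prominence.** The saddle between the peaks is the
  maximin pass: the highest threshold at which the two peaks become one
  component, found by a descending-threshold union-find merge
  (`find_saddle_point()`; its value is checked in the tests against an
  independent widest-path oracle). A genuinely separate structure is
  connected through a pass well below both peaks, whereas a shallow dip is
  internal heterogeneity of a single structure — a necrotic core seen in
  projection produces exactly such a dip. A neighbour therefore counts as
  attached only when the saddle drops below `saddle_prominence_frac`
  (default 0.85) of the lower peak. Without this test the separation
  mechanism will happily cut a necrotic tumor through its own middle.
* **Separation.** The tangent line through the saddle, perpendicular to
  the peak-to-peak segment (geometry in mm, so anisotropic grids are
  respected), splits the plane; the ROI is the seed's component of the
  isocontour, intersected with the seed-side half-plane
  (`isocontour_roi()`). On attached axes the contour level is
  `min(saddle value, level_fraction * plane max)`: the tangent line — not
  the contour level — is what removes the neighbour, and an isocontour at
  the saddle value alone would erode the tumor silhouette whenever the
  saddle sits above the salient level (typical for bright neighbours).
* **Back-projection.** The per-axis ROIs are extruded along their own
  projection axes and intersected (`backproject_3dms()`): the tightest set
  consistent with all projections, and a guaranteed superset of any object
  that reproduces them. Its boundary is the 3-D masking surface (3D-MS).
  An empty intersection raises an error suggesting more projection
  directions — with only three views, a tumor overlapping its neighbour in
  all of them cannot be separated, a structural limit of the approach.

## Stage 2: hill-climbing shrink with a joint affinity stopping rule

The 3D-MS is a superset; stage 2 shrinks it onto the tumor boundary. Two
denoised fields drive the stopping rule: the Gaussian-filtered gradient
magnitude `g` (`sigma` = 1.5 voxels; central differences, one-sided at the
volume border to avoid wrap-around) and the box-mean SUV `fbar`
(3×3×3 box, clipped at the volume bounds). The affinity of adjacent voxels
is

$$\varphi(v_i, v_j) = \exp(-\beta\,(g(v_j) - g(v_i))), \qquad
\beta = +|\beta| \text{ if } \bar f_i > \bar f_j,\ -|\beta| \text{ otherwise (ties included)},$$

with $|\beta| = 60$ by default. Only the sign of the exponent enters a
comparison against the threshold `tau = 1`, which is why the magnitude of
$\beta$ has no effect on the segmentation — a property asserted as a test
(bit-identical masks for $|\beta| \in \{10, 60, 100\}$).

The carving loop processes front voxels in descending order of physical
distance to the seed (a priority queue; ties in the inward-neighbour
choice break by higher `fbar`, then by index, making runs deterministic).
A front voxel `v_i` with inward neighbour `v_j` freezes — it is boundary —
when the mean uptake increases inward (`fbar_j > fbar_i`: the front is on
the tumor's outer slope) and the *next* inward move from `v_j` would no
longer climb the smoothed gradient ridge
($\exp(-|\beta|(g_k - g_j)) \ge \tau$ for `v_k` the inward continuation).
The one-step lookahead keeps the frozen contour on the **outer shoulder**
of the boundary ridge rather than on its crest; this is what places the
contour's SUV in the clinically observed 15–50 %-of-SUVmax band (the crest
of a blurred edge sits near half the local edge height, i.e. at the upper
edge of that band). Frozen voxels and everything inward of them form the
tumor, so a necrotic interior — which the front never reaches — is
included by construction.

Freezing is local (per voxel), not global: a single stopping event must
not freeze the whole front, or the contour could not follow an irregular
boundary. Local sign tests, however, are fragile in flat noisy background,
where roughly a quarter of freeze tests succeed by chance; at 26-neighbour
connectivity that density of spurious frozen voxels percolates. The carved
mask is therefore regularized: a one-voxel morphological opening removes
speckle attachments, the seed's 26-connected component is kept, fully
enclosed cavities are filled (the stated goal of not excluding
inhomogeneous tumor interiors), and the result is clipped to the 3D-MS.
On noise-free scenes the regularization is essentially the identity; with
5 % noise it is what keeps the accuracy loss below the 0.05 Dice the tests
require. It can be disabled (`regularize = FALSE`).

`tau` is exposed in the configuration but defaults to 1; any other value
couples the decision to $|\beta|$ and breaks the magnitude invariance, so
1 is the only value consistent with the published behaviour of the rule.

## Sub-volume quantification and planning volumes

Within the segmented tumor, voxels are classed by the half-open ranges
(0,25%], (25%,50%], (50%,100%] of the tumor's SUVmax (a voxel at exactly
25 % is "low"; the normalizer is the SUVmax *inside the segmented tumor*,
not the scan). Components smaller than 25 voxels — a 5×5×1 cell of the
planning system's calculation grid — are not counted as isolated
sub-volumes: iterating smallest-first to a fixed point, each merges into
its "nearest" sub-volume, defined as the component sharing the largest
face-adjacent boundary; if nothing touches, the nearest centroid in mm; remaining
ties resolve to the class whose SUV-range midpoint is closest to the
component's mean SUV. The metric and tie-breaks are this package's
choices; the merge events are audited in the returned object.

Margin expansion (`expand_margin()`, default 10 mm) is a morphological
dilation with a spacing-aware ellipsoidal structuring element (inclusive
radius test on voxel centres). Because 10 mm margins of different classes
overlap, `subvolume_ptvs()` returns both the overlapping per-class volumes
and an exclusive composition with priority high > mod > low — the bundled
seven-patient planning table shows both situations (six patients' class
volumes partition their PTV exactly; one patient's overlap makes the class
percentages sum above 100).

## Evaluation metrics

Dice similarity is $2|A\cap B|/(|A|+|B|)$ (1 when both masks are empty).
The Hausdorff distance is the max of the two directed sup–inf distances
between *surface* voxel sets (foreground voxels with a 6-neighbour
background contact; volume border counts as background), in mm via the
voxel spacing — checked exactly against an $O(n^2)$ enumeration oracle on
random masks. $D_{x\%}$ is the dose received by at least $x\%$ of the
structure volume, read from the sorted voxel doses with linear
interpolation between order statistics (so a uniform dose gives exactly
that dose); `HI_RTOG = Imax/RI` with `RI` defaulting to the prescribed
dose and `Imax` to the maximum structure dose (both overridable, as the
reference isodose convention varies between clinics), and
`HI_D2,D98 = (D2 − D98)/Dp × 100`. The paired t-test uses the sample-SD
closed form with `n − 1` degrees of freedom; the tests check it to 1e-6
against an independently coded incomplete-beta continued fraction and
against `stats::t.test`.

## The phantom generator: what it emulates, and what it does not

`generate_phantom()` builds scenes from analytic ellipsoids so ground
truth is exact: lung background (SUV 0.5), a tumor with hot rim
(SUV 10 = scene SUVmax), moderate shell (60 %), necrotic core (8 % by
default — low enough that fixed 40 %/50 % thresholds must fail), an
optional adjacent organ at 90 % of the rim ("heart"), Gaussian
point-spread blur (1 voxel), optional additive Gaussian noise (clipped at
0), and an optional low-order angular modulation of the tumor radius for
lobulated margins. Two geometric choices deserve explanation:

* **Rim taper.** The viable rim's uptake peaks inside the pathological
  boundary and tapers outward over `taper_mm` (default 4 mm, a
  partial-volume length scale set by the scanner point-spread, not by
  tumor size) to `edge_frac` (default 0.5) of the peak. A rim that stayed
  at SUVmax out to the last tumor voxel would put the blurred edge
  midpoint at ~50 % SUVmax and make the clinically observed 24–38 %
  boundary band geometrically unreachable; the taper reproduces the
  configuration under which that band is actually observed.
* **Organ interface.** The "attached" scenes separate tumor and organ
  surfaces by a 1.5 mm (sub-voxel) interface. After blur the two fuse into
  a single salient component — the attached case — while a faint uptake
  valley persists at the interface: the saddle the separation mechanism
  needs. With a genuine overlap no image evidence distinguishes the
  structures and any intensity-based method must fail; that configuration
  is a limitation, not a test case.

The standard suite (`standard_phantom_suite()`) sweeps 20 scenes with
semi-axes 10–30 mm (0.9/0.8 anisotropy), core fractions 5–20 %
(anti-correlated with size), every third scene lobulated, on a 1.2 mm
isotropic grid — the working resolution after PET-to-CT up-sampling, which
the resampling tests exercise explicitly with the 4 mm PET and
(1.17, 1.17, 5) mm CT geometries. The default scene grid is 2 mm
isotropic: a 5 mm slice pitch would quantize the smallest sweep tumors to
a few slices and measure voxelization, not the method. Scene sizes keep
the full test suite under a minute per 20-scene sweep on one CPU.

What the phantoms do **not** emulate: Poisson counting noise and
reconstruction artifacts (noise is Gaussian and stationary), respiratory
motion, non-ellipsoidal anatomy, and uptake drift with acquisition time.
Passing the phantom suite therefore demonstrates the geometric and
topological correctness of the pipeline under controlled contrast — it
does not certify clinical accuracy on patient data.

## Degenerate inputs and numerical choices

SUV values must be finite and non-negative; interpolation negativity is
clipped to 0. Masks resample with nearest-neighbour only (no invented
labels). The affinity exponent is clamped at ±700 to avoid overflow.
Component analysis uses 8-connectivity in 2-D and 26 in 3-D (diagonally
attached hot regions stay "attached" — the conservative choice for
separation); the shrink front propagates with 6-connectivity by default.
A seed below the salient level, below a threshold-baseline's threshold, or
outside the volume raises an informative error rather than an empty mask.
The boundary-SUV band is summarized per scene by the mean over surface
voxels; individual surface voxels straddle the contour by construction, so
their values spread about ±15 percentage points around that mean on a
1.2 mm grid, and the band statistic is evaluated on scenes where the tumor
meets background — where it abuts another hot organ the interface SUV is
set by the organ, not by the delineation.

## Known limitations

* Three projection directions cannot separate structures that overlap in
  every view; more directions would be needed.
* The boundary contour sits one voxel outside the gradient ridge by
  design; for tumors a few voxels across this shoulder is a measurable
  fraction of the radius (the suite's smallest scenes bound the effect).
* Tumors smaller than roughly twice the point-spread FWHM are dominated by
  partial volume: their boundary-SUV fractions rise above the clinical
  band regardless of contour placement.
* The minimum-size merge rule's "nearest" metric and tie-breaks are
  package choices; alternative conventions will re-assign borderline
  components.
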