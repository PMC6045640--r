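# mtvseg

Automated delineation and metabolic-heterogeneity quantification of lung
tumors on FDG-PET, for radiation dose-escalation ("dose painting") planning.

## The problem

On an FDG-PET scan the metabolic tumor volume (MTV) stands out as a
high-uptake region, but two things defeat simple SUV thresholding:

* the tumor may lie **against another hot structure** (myocardium,
  mediastinum), so a threshold region bleeds into the neighbour;
* the tumor may have **heterogeneous uptake** — a hot viable rim around a
  low-uptake necrotic interior — so a fixed fraction of SUVmax (the common
  40 %/50 % "RG40/RG50" rules) excludes the necrotic part of the tumor.

`mtvseg` implements a two-stage delineation that addresses both, then
partitions the tumor into metabolic sub-volumes for dose-escalation
planning and evaluates segmentations and treatment plans quantitatively.

## The method

**Stage 1 — separation by projection masks.** Maximum-intensity projections
(MIPs) along x, y, z turn the 3-D scene into three 2-D images on which
high-uptake structures are salient. If the tumor is attached to a
neighbouring hot structure, the two peaks are connected through a *saddle
point* — the lowest intensity on the highest pass between them. The
isocontour through the saddle and the tangent line through it
(perpendicular to the peak-to-peak axis) separate the two structures on
each MIP; back-projecting the per-axis ROI masks and intersecting the
extrusions yields a **3-D masking surface (3D-MS)** that contains the whole
tumor and excludes the neighbour.

**Stage 2 — hill-climbing shrink.** The 3D-MS shrinks onto the tumor
boundary. Adjacent voxels v_i, v_j are compared through the joint
gradient/intensity affinity

    phi(v_i, v_j) = exp(-beta * (g(v_j) - g(v_i))),    beta = +|beta| if fbar_i > fbar_j, else -|beta|

where `g` is the Gaussian-filtered gradient magnitude (sigma = 1.5 voxels)
and `fbar` the mean SUV in the 3x3x3 box around a voxel. An inward-moving
front starts at the 3D-MS surface and is carved away voxel by voxel
(farthest from the seed first); a front voxel freezes when the mean uptake
rises inward while the smoothed gradient magnitude stops rising — the
boundary ridge has been reached. Only the *sign* of beta enters the
decision, so the magnitude |beta| (default 60) does not change the result.
Because the front stops at the boundary ridge from outside, low-uptake
necrotic interiors are never excluded.

**Quantification.** The segmented tumor is split into low / moderate / high
metabolic sub-volumes by the half-open SUV ranges (0,25%], (25%,50%],
(50%,100%] of SUVmax; components smaller than a 5x5x1 planning-grid cell
(25 voxels) merge into their nearest sub-volume. Margin expansion (10 mm)
builds planning target volumes, and DVH metrics (D2, D98, Dmean, Vx),
heterogeneity indexes (HI_RTOG = Imax/RI, HI_D2,D98 = (D2-D98)/Dp x 100)
and paired t-tests support plan comparison. Dice similarity and Hausdorff
distance (in mm) evaluate segmentation accuracy.

A synthetic-phantom generator (`phantom_spec()`, `generate_phantom()`)
produces PET scenes with analytic ground truth — heterogeneous tumor,
adjacent hot organ, lung background, point-spread blur, noise — so every
stage is testable without patient data.

## Worked example

```r
library(mtvseg)

spec <- phantom_spec(grid_shape = c(80, 80, 80), spacing = c(1.2, 1.2, 1.2),
                     tumor_radii_mm = c(16, 14.4, 12.8), organ = TRUE,
                     rng_seed = 42)
ph  <- generate_phantom(spec)         # scene + analytic ground truth
seg <- segment_tumor(ph$vol, ph$seed) # two-stage delineation
print(seg)
#> PET tumor segmentation (MIP separation + hill-climbing shrink)
#>   tumor volume : 7732 voxels = 13.36 ml
#>   SUVmax       : 8.503
#>   seed voxel   : (40, 40, 40)
#>   masking surface: 9412 voxels

part <- merge_small_components(partition_subvolumes(ph$vol, seg$tumor), 25)
measure_subvolumes(part)
#> total tumor volume: 13.36 ml
#>  class   ml percent
#>    low 0.68    5.07
#>    mod 2.85   21.31
#>   high 9.84   73.62

evaluate_segmentation(seg$tumor, ph$truth_tumor)
#> DSC 0.959 | HD 1.20 mm
```

The tumor volume is recovered with Dice 0.959 against the analytic truth
even though it touches a high-uptake "heart" (zero overlap with the organ
core) and contains a necrotic interior at 8 % SUVmax (fully included —
exactly the case in which RG40/RG50 thresholding fails). The sub-volume
report gives the low/moderate/high metabolic volumes a dose-escalation plan
would boost differentially.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/mtvseg segment --in pet.nii.gz --seed 40,40,40 --out tumor.nii.gz
Rscript inst/cli/mtvseg run --in pet.nii.gz --seed 40,40,40 --out-dir results/
```

(installed: `Rscript $(Rscript -e 'cat(system.file("cli","mtvseg",package="mtvseg"))') ...`).

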