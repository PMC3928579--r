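---
title: "Methods: automatic ONH morphometry and the BGA score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic ONH morphometry and the BGA score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhbga)
```

# The problem and the model

Structural OCT examination of the optic nerve head (ONH) has to substitute
for perimetry whenever a visual-field test is unreliable. The pipeline in
this package turns an ONH-centred OCT volume into a single severity index
by chaining classical image-analysis primitives, each keyed to a physical
property of the retina:

* the **RPE** is the brightest reflector of a B-scan, so its position per
  A-scan is a per-column brightness argmax of the median-filtered volume;
* at the **disk** the RPE terminates and the detected brightest reflector
  shifts posteriorly (into the excavation), so the disk footprint is the
  set of en-face columns whose detected row departs from the mean row;
* the **ILM** is the first bright interface above the RPE, recovered from
  an Otsu binarization of the supra-RPE region;
* the lower **RNFL** boundary is the first light-to-dark gradient edge
  strictly inside the open (ILM, RPE) band, subsequently repositioned by
  an *active edge correction* (below);
* the **cup** is the part of the disk where the ILM dips below a reference
  chord drawn between the RPE at the disk margins and displaced 150 µm
  anteriorly — the standard reference-plane convention of clinical cup
  delineation;
* the peripapillary **thickness profile** is the RNFL thickness resampled
  over angle on the annulus `[2 r_disk, 3 r_disk]`.

Three dimensionless features — cup-centroid eccentricity `w_g(1)`,
cup-to-disk boundary proximity `w_g(2)`, and mean absolute relative RNFL
deviation from a normative profile `w_g(3)` — are averaged into the
biomorphological glaucoma advancement ratio `w_BGA`, and the expected
perimetric mean defect follows the affine conversion
`MD = slope · w_BGA + intercept` with the published coefficients
(24 dB per unit, −9.34 dB) as configurable defaults.

The assumptions are explicit: one connected disk per volume; an RPE that
is the global brightness maximum of each A-scan outside the disk; a cup
expressed as an ILM excursion deeper than the reference plane; and an
approximately isotropic en-face sampling wherever pixel-based radii are
interpreted geometrically (see *Units* below).

# Tunable parameters

All constants live in `onh_config()` (file round trip via
`write_config()`/`read_config()`), never in code:

| parameter | default | units | role |
|---|---|---|---|
| `median_mask` | 3×3×3 | px | pre-filter neighbourhood; pools adjacent B-scans |
| `p_m` | 2/3 | — | disk threshold fraction |
| `disk_threshold_mode` | `reciprocal` | — | see *Disk threshold reading* |
| `otsu_scope` | `bscan` | — | Otsu sample per B-scan or per volume |
| `gradient_floor` | 2 | gray | minimum edge magnitude; 0 = strict positive-gradient rule |
| `refine_window` | 5 | px | height of each averaging window in the edge correction |
| `cup_offset_um` | 150 | µm | anterior displacement of the cup reference chord |
| `polar_bins` | 360 | — | angular resolution (1°) of the thickness profile |
| `min_valid_fraction` | 0.5 | — | samples a bin needs to count as valid |
| `md_slope`, `md_intercept` | 24, −9.34 | dB | BGA→MD line; replaceable by a re-fitted model |

The gradient floor exists because a literal "any positive gradient" rule
fires on the first noise voxel below the ILM in any image with nonzero
noise; 2 gray levels is small against the ~110-gray band-to-background
contrast yet above the residual noise of the median-filtered volume.
Setting it to 0 restores the strict rule.

# Design choices at genuinely open points

**Disk threshold reading.** Flagging columns with `row > (2/3)·mean(row)`
selects nearly every column of any plausible geometry, which contradicts
the threshold's stated purpose of capturing the *maximum acceptable shift*
of the reference layer at the disk. The default therefore flags columns
deeper than `mean/p_m` (a 50 % depth excursion at `p_m = 2/3`), which
isolates the excavated region; `disk_threshold_mode = "literal"` restores
the verbatim rule for comparison.

**Target of the edge correction.** The correction is defined for any
contour; the package applies it to the RNFL lower boundary, whose gaps
under vessel shadows are the documented failure mode it repairs, and keeps
`refine_contour()` generic so it can be pointed at other boundaries.

**Search range and clamp.** Candidate offsets span ± the per-B-scan median
ILM–RPE separation. Candidate *positions* are additionally clamped to the
open (ILM, RPE) band, mirroring the protections of the initial edge
search: without the clamp the range reaches the RPE, whose light-to-dark
edge has roughly twice the contrast of the RNFL edge and would capture the
objective. Window heights are not specified anywhere authoritative; 5 px
per side resolves a 10 px (50 µm at 5 µm/px) band reliably and is
config-exposed.

**Otsu ties.** A perfectly bimodal sample has a plateau of cuts with equal
between-class variance; returning the smallest maximizer would put the
threshold *at* the lower mode. The implementation returns the mean of the
tied maximizing levels, placing the cut centrally between modes.

**Boundary pixels for `r_min`.** Mask boundaries are pixels with a
4-adjacent background neighbour — the boundary dual to an 8-connected
foreground region. Including diagonal adjacency would also flag pixels a
full diagonal step inside a rasterized rim (for an r = 20 disk, pixels at
radius ≈ 18.8 near 45°), systematically biasing the minimum
boundary-to-boundary distance low by up to ~1.2 px.

**Cup-offset monotonicity.** Raising the reference plane (a larger
anterior offset) can only admit more of the dipping ILM, so the cup area
is non-decreasing in the offset; the tests assert this direction.

**Units and anisotropy.** Angular/radial resampling is laid out in
physical micrometres: when the lateral and B-scan spacings differ the
annulus is elliptical in pixel space, and the pixel-based equivalent disk
radius is converted through the geometric mean of the two lateral scales.
The ratio in `w_g(3)` is unit-free either way. Default phantoms sample the
en-face plane isotropically so the two conventions coincide exactly.

**Quadrants.** TE/SU/NA/IN are fixed 90° sectors with the temporal sector
centred at θ = 0 for a right eye (`eye = "left"` mirrors the horizontal
labels). θ follows `atan2(n − n₀, i − i₀)`: a displacement towards larger
A-scan index maps to θ = 90°.

**Indexing.** All internal indices are 1-based (the R convention, shared
by every imaging package used); file outputs state the convention in a
header comment so downstream consumers in 0-based languages can convert
deliberately rather than accidentally.

**Empty cup.** A shallow nerve head whose ILM never crosses the reference
plane yields an empty cup mask — a valid healthy finding, not an error.
The geometry then reports the cup centroid at the disk centroid with
`r_min = r_disk`, so both `w_g(1)` and `w_g(2)` are 0.

# The phantom generator

`phantom_spec()` describes a synthetic ONH scene; `generate_phantom()`
renders it and returns exact ground truth (surfaces, masks, analytic
feature values). The scene emulates precisely the properties the pipeline
keys on:

* a bright RNFL band starting at the ILM with a sharp lower edge at the
  prescribed thickness, which may vary with angle around the disk;
* a Gaussian-profile RPE band (σ = 2 px) that is the global brightness
  maximum, absent inside the disk where a deeper bright band (the
  excavation floor) takes over;
* a steep-walled ILM dip of prescribed depth inside the cup and a thin
  membrane across the disk opening;
* optional multiplicative vessel shadows below the ILM, which reproduce
  the contour-gap failure mode of the raw edge search;
* additive Gaussian noise clipped to the 8-bit range.

Default conditions: 256 × 256 × 64 voxels at 5 µm axial and 12 µm
isotropic en-face sampling, ILM at row 40, 100 µm RNFL, RPE at row 120,
disk radius 20 px, cup radius 10 px, 400 µm cup depth, 450 µm excavation
— sizes chosen so a full render-plus-analysis cycle takes a few seconds
and a 20-member phantom family stays comfortably inside a routine test
run, while keeping every structure several pixels wide. The 2r–3r annulus
exits the 64-B-scan extent for angles near the slice axis; those bins are
flagged invalid, and the deviation score normalizes over valid bins, so a
uniformly scaled reference yields exact scores under partial coverage.

What the phantom deliberately does **not** emulate: OCT speckle (noise is
additive Gaussian, not multiplicative), eye motion and registration
artefacts, tilted discs, peripapillary atrophy, and non-circular cups.
Passing the phantom suite therefore demonstrates correctness of the
geometry and of every algorithmic step under controlled contrast — it
does not certify segmentation accuracy on pathological clinical scans.

After the 3×3×3 median filter a symmetric axial peak acquires a 3-row
plateau, so the detected RPE sits one row anterior to the rendered peak;
the phantom tolerances (±1 px for RPE/ILM, ±2 px for the corrected RNFL,
at ≥99 % of columns) account for this quantization, and the analytic
scores are met within ±0.05 (`w_g(1)`, `w_g(2)`) and ±0.03 (`w_g(3)`).

# Numerical choices and degenerate inputs

* **RPE tie-break**: among tied per-column maxima, the row nearest the
  median of the already-unambiguous 5×5 en-face neighbourhood wins;
  without any solved neighbour, the smallest row. All-zero columns are
  undefined.
* **Surface gaps** propagate as `NA` sentinels; the edge correction (and
  only it) bridges gaps by linear interpolation before optimizing, so its
  output is continuous wherever the band is defined.
* **Empty band** (ILM meeting RPE) and featureless bands (no gradient
  above the floor) leave the RNFL undefined rather than guessing.
* **Offset ties in the correction** are broken towards the smallest
  absolute offset, so a contour already on the best edge is returned
  unchanged.
* **Degenerate Otsu input** (a constant sample) raises an error at the
  operation level; a flat B-scan simply leaves its columns undefined at
  the pipeline level.
* **Factor analysis**: constant features are dropped with a warning,
  missing values use pairwise-complete correlations, eigenvalues are
  clipped at 0, and a Kaiser cut falling within 0.1 of an eigenvalue of 1
  is flagged ambiguous. Varimax rotation preserves communalities to
  numerical precision; class signs are oriented so each class's dominant
  feature loads positively.
* **Problem sizes in the test-suite**: module tests use a reduced
  200 × 96 × 32 phantom (~1 s per analysis); the recovery suite uses the
  default 256 × 256 × 64 conditions across 20 phantoms; oracle-equivalence
  suites run 100 random instances per primitive on small arrays;
  regression recovery uses 100 replicates of 110-eye cohorts.

# Synthetic cohorts for the statistical module

`simulate_md_cohort()` draws BGA ratios uniformly on [0, 1] and generates
MD from the configured line plus Gaussian scatter; the default 4.1 dB
scatter reproduces the typical strength of this structure–function
correlation (about 0.86 at n = 110). `simulate_feature_cohort()` plants an
exact block structure of latent classes for validating loading recovery.
These generators define the study conditions of the statistical tests;
they are not fitted to data.

# Known limitations

* The disk model assumes a single connected excavation; multiple equal
  candidate regions are resolved by area only.
* The cup reference chord is per-B-scan and linear; strongly tilted nerve
  heads would need a planar or curved reference fit.
* `w_g(3)` is unclamped (thickness beyond twice the reference exceeds 1),
  so `w_BGA ∈ [0, 1]` is guaranteed only while `w_g(3) ≤ 1`.
* The MD conversion is a fixed affine model; refitting it to a local
  cohort (`fit_bga_md_regression()`) and dropping the coefficients into
  the config is the intended calibration path.
* JPEG B-scan stacks are not read (no JPEG reader among the declared
  dependencies); PNG or TIFF stacks are.
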