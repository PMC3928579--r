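# onhbga

Automatic morphometry of the optic nerve head (ONH) in 3-D OCT volumes, and
a single biomorphological score of glaucoma advancement with a linear
conversion to the expected visual-field mean defect.

## Who this is for

Glaucoma severity is normally staged with static perimetry, but a reliable
visual-field test is impossible for many patients (advanced AMD, poor
fixation, low compliance). In those eyes the structural examination — the
optic disk, its cup, and the peripapillary retinal nerve fibre layer
(RNFL) — has to carry the assessment. This package implements a fully
automatic structural pipeline for researchers working with ONH-centred OCT
volumes: from raw B-scan stacks to layer boundaries, disk/cup geometry, a
TSNIT thickness profile, and a scalar severity index.

## The method

Each A-scan column of the median-filtered volume `L_M(m,n,i)` is processed
per B-scan:

1. **RPE** — the brightest layer: `L_RPE(n,i) = argmax_m L_M(m,n,i)`, with
   ties resolved towards the neighbouring columns' solution.
2. **Disk** — en-face columns whose RPE row departs from the mean row
   beyond a threshold (the bright reference layer terminates and the
   detected maximum shifts posteriorly inside the disk opening), followed
   by largest-component/fill-hole cleanup.
3. **ILM** — Otsu binarization of the region above the RPE; the first
   foreground row per column.
4. **RNFL lower boundary** — the first light-to-dark Prewitt edge strictly
   between ILM and RPE, then an *active edge correction*: each contour
   point is moved to the row maximizing the mean-brightness difference
   between a window just above and just below, which bridges and repairs
   gaps from vessel shadows.
5. **Cup** — disk columns whose ILM falls posterior to the RPE chord
   displaced 150 µm anteriorly.
6. **Polar ROI** — RNFL thickness resampled on the annulus between
   `2·r_disk` and `3·r_disk` in 1° bins (TE/SU/NA/IN quadrants).

Three normalized features summarize the damage:

    w_g(1) = |c_cup − c_disk| / r_disk          (cup eccentricity)
    w_g(2) = 1 − r_min / r_disk                 (cup-to-disk boundary proximity)
    w_g(3) = mean_θ |L(θ) − L_ref(θ)| / L_ref(θ) (RNFL deviation from reference)

    w_BGA  = (w_g(1) + w_g(2) + w_g(3)) / 3

and the expected perimetric mean defect follows the linear conversion

    MD = 24 · w_BGA − 9.34   [dB]

Because patient volumes cannot be shipped, the package includes a phantom
generator (`phantom_spec()` / `generate_phantom()`) that renders synthetic
ONH volumes — layered bright bands, disk excavation, cup dip, vessel
shadows, noise — together with the exact surfaces, masks and analytic
feature values they encode, so every stage is testable against ground
truth. An exploratory factor-analysis module (`fit_factor_model()`,
`class_perimetry_correlation()`, `fit_bga_md_regression()`) reproduces the
feature-selection methodology on morphometric tables.

## Worked example

```r
library(onhbga)

# an eye with an enlarged, slightly eccentric cup and diffuse RNFL thinning
spec <- phantom_spec(cup_radius_px = 14, cup_center = c(131, 32),
                     rnfl_thickness_um = 70)
ph  <- generate_phantom(spec)
res <- onh_analyze(ph$volume)
print(res)
```

```
Optic nerve head analysis
disk: centre (128.00, 32.00), r = 19.97 px
cup:  centre (131.00, 32.00), r = 13.92 px, r_min = 2.83 px
w_g(1) = 0.1502  w_g(2) = 0.8584  w_g(3) = 0.3000
w_BGA  = 0.4362  ->  expected MD = 1.13 dB
```

The cup centroid sits 3 px temporal to the disk centroid (`w_g(1) ≈ 0.15`),
its rim approaches the disk boundary to within 2.8 px (`w_g(2) ≈ 0.86`),
and the peripapillary RNFL runs 30 % below the 100 µm reference
(`w_g(3) = 0.30`). The phantom's analytic truth for this geometry is
`w_g = (0.150, 0.850, 0.300)`, `w_BGA = 0.433` — the pipeline recovers it
to within half a percent of the disk radius. `plot(res)` draws the en-face
disk/cup footprint and the TSNIT profile against its reference;
`write_results(res, "out/")` persists surfaces (CSV), masks (PNG) and the
feature row.

A shell interface wrapping the same functions ships in `exec/onh`:

```sh
onh phantom --out ph/                # render the default phantom + truth
onh segment --volume ph/volume.tif --calibration cal.ini --out seg/
onh factor  --table cohort.csv --md 'w(29)' --out fa/
```

A synthetic TSNIT-style normative profile for `--reference` /
`read_reference_profile()` is bundled at
`inst/extdata/reference_tsnit_synthetic.csv`.

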