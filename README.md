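# glomorph

3D morphometry of kidney glomeruli in light-sheet microscopy volumes, plus
the image metrics used to benchmark optical tissue clearing.

## The problem

Optical clearing makes whole organs transparent enough for light-sheet
fluorescence microscopy (LSFM), and lipophilic membrane dyes such as DiI
label the vasculature — including the glomeruli, the kidney's filtration
tufts, which appear as bright ellipsoidal *heads* hanging from vascular
*necks*. Comparing healthy kidneys with disease models (e.g. nephrotoxic
nephritis, NTN, which enlarges glomeruli) requires turning those volumes
into per-glomerulus numbers. glomorph implements that computation as a
reusable, fully tested R pipeline:

- **Detection** — z-interpolation of the anisotropic stack (4 µm plane
  intervals are typical) to isotropic voxels, global Otsu thresholding,
  morphological geodesic active contour refinement, and watershed /
  ellipsoid-fit instance separation with edge-of-stack exclusion.
- **Meshing** — marching-tetrahedra isosurfaces of each instance (always
  watertight), curvature-flow smoothing, hole filling, and enclosed volume
  by the divergence theorem.
- **Morphometry** — the anchor points (central base point, centroid, tip),
  the orientation axis, a stepped cross-section profile with exact Feret
  (caliper) widths per step, and from it the features
  `volume`, `hMax`, `hMin` (max/min diameter of the thickest head
  cross-section between centroid and tip), `nMax` (max neck diameter), and
  the medial curve length `L`.
- **Clearing metrics** — linear expansion `sqrt(post/pre area)` from
  silhouette outlines, relative grid transmittance, spectral transmittance
  against a blank, day-0-normalized fluorescence retention, depth-resolved
  SNR from perpendicular dendrite profiles, tortuosity `d/D`, rigid image
  alignment and binary SSIM.
- **Statistics** — Shapiro–Wilk normality reporting, Welch/Student t-tests,
  one-way ANOVA + Tukey HSD, significance stars, and an end-to-end
  synthetic normal-vs-NTN cohort experiment.
- **Synthetic data** — a seeded phantom generator (3D kidney stacks with
  analytic ground truth; 2D outline, transmittance-grid and dendrite
  fixtures) so the whole chain is testable without any acquisition.

Tabular results are tibbles; fitted comparison objects support
`tidy()`/`glance()`; result types have `autoplot()` methods.

## Worked example

```r
library(glomorph)

# a synthetic kidney stack: 3 glomeruli, 4 µm plane interval, 1 µm pixels
spec <- phantom_spec(grid_shape = c(50, 180, 180), voxel_size = c(4, 1, 1),
                     n_glomeruli = 3, seed = 1)
ph <- generate_kidney_phantom(spec)
ph$volume
#> <volume_stack> 50 x 180 x 180 voxels (z,y,x), spacing 4/1/1 um
#>   intensity range [0, 3210]  kidney phantom seed 1

labels <- segment_glomeruli(ph$volume)   # isotropic + Otsu + GAC + watershed
labels
#> <label_map> 197 x 180 x 180 voxels (z,y,x), 3 instance(s)

feats <- features_from_labels(labels)
feats[, c("id", "volume_um3", "hmax_um", "nmax_um", "L_um")]
#> # A tibble: 3 × 5
#>      id volume_um3 hmax_um nmax_um  L_um
#>   <int>      <dbl>   <dbl>   <dbl> <dbl>
#> 1     1    137882.    65.0    15.8  99.2
#> 2     2    128682.    64.4    15.7 106.
#> 3     3    103928.    60.2    16.1 101.

ph$truth[, c("id", "head_volume_um3", "dmax_um", "neck_diameter_um")]
#> # A tibble: 3 × 4
#>      id head_volume_um3 dmax_um neck_diameter_um
#>   <int>           <dbl>   <dbl>            <dbl>
#> 1     1          98938.    61.1             15.0
#> 2     2         124347.    69.6             15.1
#> 3     3         134701.    64.4             14.5
```

Instance labels come out in watershed order, not placement order — match
them to the truth table by centroid (the `fits` attribute of the label map
carries per-instance centroids) before comparing row by row. Matched up,
the recovered volumes here are 2–5 % above the analytic ground truth
(marching a binary field slightly over-reads radii; smoothing pulls some of
that back), and `hMax`/`nMax` land within a few percent of the true head
and neck diameters.

A two-arm experiment emulating glomerular enlargement:

```r
cohort_spec <- phantom_spec(grid_shape = c(55, 160, 160),
                            voxel_size = c(4, 2, 2), n_glomeruli = 10,
                            seed = 1)
ex <- run_cohort_experiment(cohort_spec, effect = c(head = 1.3, neck = 1.3),
                            n_per_group = c(2, 1),
                            n_sample_per_volume = c(9, 10), seed = 23)
tidy(ex)[, c("feature", "p_value", "stars", "measured_ratio", "expected_ratio")]
#> # A tibble: 3 × 5
#>   feature         p_value stars measured_ratio expected_ratio
#>   <chr>             <dbl> <chr>          <dbl>          <dbl>
#> 1 volume_um3 0.0000000878 ***             2.06           2.20
#> 2 hmax_um    0.00000492   ***             1.27           1.3
#> 3 nmax_um    0.0000154    ***             1.30           1.3
autoplot(ex)   # jittered per-glomerulus values with mean ± SD and stars
```

A 1.3× linear effect should roughly triple volume (1.3³ ≈ 2.20) and scale
the diameters by 1.3; the pipeline recovers all three and flags them
significant with 18 vs 10 sampled glomeruli.

There is also a thin command line (`inst/cli/glomorph`) with
`simulate`, `segment`, `features`, `metrics`, `compare` and `experiment`
subcommands; every run writes a JSON sidecar of its effective parameters.

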