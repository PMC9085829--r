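---
title: "Methods: glomerulus morphometry and clearing metrics in glomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glomerulus morphometry and clearing metrics in glomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomorph)
```

## What the package computes

glomorph quantifies glomeruli in light-sheet fluorescence microscopy (LSFM)
volumes of optically cleared, membrane-dye-labelled kidneys. A glomerulus in
such data is a bright, roughly ellipsoidal capillary tuft (the *head*)
hanging from a vascular stalk (the *neck*). The package implements the full
chain from a raw anisotropic z-stack to per-glomerulus 3D features —
enclosed volume, maximum/minimum head diameter (`hMax`, `hMin`), maximum
neck diameter (`nMax`), the arc length `L` of the medial curve, and the
orientation axis — together with the 2D image metrics used to benchmark
optical clearing protocols (linear expansion, relative and spectral
transmittance, fluorescence retention, depth-resolved SNR, dendrite
tortuosity, binary SSIM) and the group-comparison statistics used to contrast
healthy and nephritic (NTN-model) kidneys.

No public volumes accompany this kind of study, so the package ships a
seeded synthetic phantom generator with analytic ground truth. Every claim
the test suite makes is a claim about recovery of known geometry, not about
any particular specimen.

## The detection chain

`segment_glomeruli()` composes four steps, each exported on its own:

1. **Isotropic resampling** (`interpolate_isotropic()`). LSFM stacks are
   sampled at 4 µm plane intervals but ~1 µm in-plane. Each coarse axis is
   linearly interpolated onto the finest spacing. Linear (order-1)
   interpolation is deliberate: it preserves the intensity range and
   introduces no ringing at blob edges, and the physical extent is kept
   exactly, so all downstream features are in true micrometres.
2. **Global Otsu binarization** (`binarize_otsu()`). The threshold maximizes
   between-class variance on a 256-bin global histogram. Bright foreground
   is the default (membrane dyes are bright); a dark-foreground flag covers
   inverted material. A constant volume has no threshold and is an error.
3. **Geodesic active contour** (`refine_geodesic_active_contour()`), a
   morphological level-set: the edge-stopping function is
   `g = 1/sqrt(1 + (|∇I_σ|/λ)²)` with σ = 1 voxel of Gaussian pre-smoothing
   and λ set to a third of the 99th percentile of gradient magnitude; per
   iteration a mild negative balloon erodes flat regions (where `g > 0.7`),
   an attraction term moves the front along `∇g`, and one 26-neighbourhood
   majority pass applies discrete curvature flow. Defaults: 50 iterations,
   balloon −1, smoothing 1. None of these is specimen-calibrated; all are
   arguments.
4. **Instance separation** (`separate_instances_ellipse_fit()`). A true-3D
   anisotropy-aware Euclidean distance transform is watershed-flooded from
   its thinned local maxima (minimum seed height 12 µm — above any plausible
   neck radius, below any plausible head radius; minimum seed separation
   20 µm). Each region is then *gated*, not reshaped, by a second-moment
   ellipsoid fit: for a uniform ellipsoid the covariance eigenvalues are
   `a²/5`, so the fitted semi-axes are `sqrt(5λᵢ)`. A candidate survives if
   its volume ≥ 1000 µm³, its semi-axis ratio ≤ 3 (rejects vessel
   fragments), and its fit residual — defined scale-free as 1 − Jaccard
   overlap between the candidate and its fitted ellipsoid — is ≤ 0.4.
   Finally `exclude_edge_objects()` removes instances within a margin of the
   stack faces (default 5 % of each axis extent), standing in for the
   interactive proofreading a human operator would do near acquisition
   artifacts, and `sample_glomeruli()` draws the ten-per-kidney random
   selection reproducibly.

## Meshing and features

`mesh_from_label()` runs marching tetrahedra — the Kuhn 6-tetrahedron cell
decomposition, an ambiguity-free member of the marching-cubes family — on
the binary instance field at iso-level 0.5, padded by one background voxel
so the surface always closes watertight with consistent outward normals.
Meshing the binary field rather than raw intensity keeps mesh and label map
exactly consistent; the boundary decision is made once, by the contour
stage. `smooth_curvature_flow()` then applies explicit umbrella-Laplacian
mean-curvature steps (default 10 iterations of step 0.1, chosen so a
sphere's volume drifts by well under 5 %, which the tests enforce); the
triangle list never changes, and a step that inverts a triangle aborts with
advice. `ensure_closed()` fan-triangulates boundary loops from their
centroids and re-orients globally; `mesh_volume()` is the signed sum of
origin tetrahedra (translation-invariant by construction, enforced to 1e-6
relative).

`glomerulus_features()` composes the morphometry: the three anchor points
(central base point, volume centroid, tip), the orientation (base →
centroid, normalized), a stepped profile (vertices binned every
`step_height` along the axis, default twice the in-plane voxel size; each
step records its vertex centroid and its maximum/minimum Feret width in the
plane normal to the axis, computed exactly on the 2D convex hull), and from
it `L` (polyline length through non-empty step centroids), `hMax`/`hMin`
(max and min width of the thickest step between centroid and tip, ties
broken toward the centroid) and `nMax` (maximum width over the neck span).
Empty steps are kept as explicit gaps.

Two points were genuinely open and are worth recording:

* **Base point.** A mesh cut from its attachment has an open boundary loop
  whose centroid is the natural base. Pipeline meshes, however, are closed
  by construction, so the pipeline uses `base_reference = "auto"`: the
  vertex farthest from the volume centroid. For a head-dominant shape the
  centroid sits inside the head and the farthest vertex is the distal neck
  end, which is exactly the base. A closed mesh with no reference at all is
  an error rather than a guess.
* **Head/neck partition.** "Thickest part between centroid and tip" defines
  the head span, but nothing in the source workflow delimits the neck. A
  fixed fraction of the centroid projection (0.8) misclassifies the lower
  head as neck whenever the neck is long relative to the head, which is the
  geometry glomeruli actually have; `nMax` then reads a head width. The
  default is therefore the *mirror rule*: the head is treated as symmetric
  about its centroid, so its onset is the tip reflected through the
  centroid, `max(0, 2·s_centroid − s_tip)`, and the neck span runs from the
  base to that onset. The mirror rule in turn assumes head symmetry along
  the axis; a head tilted against its neck breaks it by up to the
  difference of its semi-axes, letting junction "shoulder" steps (widths
  ~0.65 × hMax) leak into the neck span. A width cap closes that gap with
  an anatomical prior: walking up from the base, the neck ends at the first
  step wider than `width_cap × hMax`. The default 0.55 sits strictly above
  0.5 — a neck can legitimately reach half its head's width — and below the
  shoulder widths a junction projects. Both the fraction rule
  (`head_onset = "fraction"`) and `width_cap = NULL` are available for
  sensitivity analysis. `hMin` is computed and reported but is not part of
  the headline three-feature comparison.

## The phantom generator

`phantom_spec()` + `generate_kidney_phantom()` define the study conditions:
heads are random ellipsoids (semi-axes Gaussian, default mean 30 µm, SD
3 µm — a 60–80 µm tuft, the scale of a mouse glomerulus), necks are
cylinders (radius mean 7 µm, SD 0.7 — arteriolar calibre; length mean
30 µm, SD 4) rendered at head intensity since both are membrane-labelled,
and a random branching tree of dimmer 3 µm capsules provides vascular
distractor foreground at a target volume fraction. Default contrasts
(background 100, vessels 400, heads 3000, Gaussian noise SD 50, optional
Poisson) are free parameters of the phantom — the source study publishes no
intensity statistics — chosen to give strong but not trivial contrast.
Geometry is rasterized with a one-voxel soft edge on a fine isotropic grid
at the in-plane spacing, blurred by an isotropic Gaussian PSF (default σ
1 µm), resampled to the anisotropic target grid (default 4 µm plane
interval), and only then corrupted by noise, so ground truth is exact by
construction. Placement is a jittered lattice with pitch two maximal head
radii (draws truncated at mean + 2 SD so the `phantom_spec()` capacity
check is a guarantee); necks must clear every other head, keeping instance
ground truth unambiguous. Identical specs and seeds are bit-identical.

What the phantoms do **not** emulate: stripe artifacts, depth-dependent
attenuation, spatially varying PSFs, vascular anatomy beyond random
capsule trees, or touching glomeruli. Passing recovery tests therefore
demonstrates correctness of the measurement chain on idealized but
non-trivial data, not robustness to every acquisition pathology.

The 2D generators mirror the clearing-benchmark measurements: tissue
silhouettes on a printed grid whose post/pre area ratio is the squared
linear scale; transmittance grids whose inner lines are exactly the
attenuation times the outer lines before noise; dendrite planes whose
centerlines have known arc length and whose intensity is calibrated so the
fixed core/flank SNR estimator recovers the scheduled ratio exactly (the
estimator's core window is wider than a dendrite, so an uncalibrated peak
ratio would under-read — the calibration solves the two-window linear
system for the tube intensity).

## Statistics

`compare_two_groups()` reports per-group Shapiro–Wilk (never auto-switching
the test — the reference workflow reports none), a two-sample t-test
(Welch by default for robustness; pooled Student behind `var_equal = TRUE`,
since the source does not say which was used), and mean ± SD.
`compare_multi_groups()` is ordinary one-way ANOVA followed by Tukey HSD.
Stars follow the conventional mapping (`***` < 0.001, `**` < 0.01, `*` <
0.05). `run_cohort_experiment()` drives the end-to-end synthetic
normal-vs-NTN comparison: a two-arm cohort (the diseased arm scales head
semi-axes and neck radii by the effect factors, default 1.3), the full
pipeline per volume, up to ten sampled glomeruli per volume, per-feature
comparisons, and recovery diagnostics (measured vs expected group-mean
ratios: volume should scale as the cube of the head factor). Its
`ground_truth` mode reads features off the analytic tables without
rendering — the statistical machinery and generator can then be calibrated
with hundreds of replicates in seconds; type-I error at α = 0.05 is checked
against binomial bounds over 200 such comparisons.

## Problem sizes and numerical choices

The test suite and the acceptance script use these sizes, chosen as the
smallest that keep every recovery target comfortably resolved:
single-phantom recovery runs at the reference acquisition geometry (1 µm
in-plane, 4 µm planes, 140×140×40 grid; head ~30 voxel radius); the power
experiment runs at 2 µm in-plane (55×160×160 grid, 10 glomeruli per volume,
2 normal volumes × 9 sampled + 1 diseased volume × 10 sampled = 18 vs 10
glomeruli, 20 master seeds in the tests, 10 in the acceptance script). At
2 µm a 14 µm neck is still 7 voxels across, and recovered features stay
within a few percent of truth.

Other numerical choices: Otsu uses 256 bins; the GAC edge scale falls back
to `max/3` when the gradient is degenerate; distance-transform seeds are
thinned greedily (strongest first) with ties broken by linear index;
`feret_widths()` deduplicates points to 1e-9 before the hull; thickest-step
ties break toward the centroid; the curvature-flow error on triangle
inversion names the remedy; empty watershed results are a valid `K = 0`
label map, while an empty GAC result warns. All sampling (`sample_glomeruli`,
SNR dendrite picks, cohort seeds) derives from explicit integer seeds and
restores the caller's RNG state.

## Known limitations

Feret-based `nMax` reads the widest cross-section of the neck *span*, so a
bulbous junction can dominate a thin mid-neck; the mirror rule mitigates
but does not remove this. Marching surfaces of binary fields overestimate
radii by up to half a voxel, partially offset by smoothing shrinkage — net
volume bias on a 30-voxel-radius sphere is ~3 %. The SSIM implementation
uses edge-replicating Gaussian windows (values at the border differ
slightly from zero-padded conventions). Rigid alignment searches rotations
on a user-supplied grid; sub-degree accuracy requires a finer grid. The
statistics module intentionally implements only the workflow the source
study used; it is not a general linear-models interface.
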