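---
title: "Landmark-driven Couinaud segmentation: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-driven Couinaud segmentation: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couinaud)
```

## The problem

Planning a liver resection requires knowing how much functional liver will
remain — the future liver remnant (FLR) — and how healthy that remnant is.
Couinaud's classification divides the liver into nine functionally
independent units (segments 1, 2, 3, 4a, 4b, 5, 6, 7, 8), each with its own
vascular inflow and outflow, so any anatomical resection can be expressed as
a set of removed segments. This package partitions a 3D binary liver mask
into those nine segments from eight anatomical landmark points, reports
per-segment volumetry and per-segment medians of quantitative MRI maps (cT1
in ms, a fibroinflammation biomarker; PDFF in %, a steatosis biomarker), and
computes FLR percentages with the agreement statistics (Dice overlap,
Bland–Altman 95% limits of agreement) used to validate this class of
measurement.

## The partition model

All geometry lives in world millimetres (RAS+, the NIfTI native convention;
files in other conventions must be reoriented upstream — one convention keeps
every sign testable). The sole geometric inputs are eight named landmarks:
the superior and inferior inferior-vena-cava (IVC) points, the middle and
right hepatic veins, the gallbladder fossa, the umbilical fissure, and the
right and left portal vein branch points.

From these the package derives:

* **IVC axis** — from the inferior IVC point toward the superior one.
* **Main (Cantlie) plane** — the least-squares plane *containing the IVC
  axis* through the middle hepatic vein and the gallbladder fossa; positive
  side = patient right. Among planes containing a fixed axis, the
  least-squares fit has a closed form: express target offsets in an
  orthonormal basis of the axis-orthogonal plane and take the smallest
  eigenvector of their 2×2 scatter.
* **Right plane** — axis-plane through the right hepatic vein (positive =
  anterior); **left plane** — axis-plane through the umbilical fissure
  (positive = medial).
* **Two portal planes** — perpendicular to the IVC axis through the right
  and left portal vein landmarks (positive = superior). Using two transverse
  planes rather than one oblique plane lets the right and left hemilivers be
  divided at their own portal heights, which matches how the landmarks are
  defined; a single oblique plane would leave one of the two portal
  landmarks unused.
* **Caudate cylinder** — everything within `caudate_radius_mm` (default
  30 mm) of the IVC axis is segment 1, evaluated *before* any plane split,
  because the caudate straddles Cantlie's plane anatomically. No published
  landmark rule defines the caudate boundary; a single interpretable radius
  is the simplest rule consistent with the tight segment-1 agreement seen in
  practice, and it is configurable.

Classification of a point is then a fixed decision tree: caudate first, then
main plane (right/left), then right or left plane (anterior/posterior or
medial/lateral), then the corresponding portal plane (superior/inferior).
Signed distances of exactly zero count as the positive side, making the
classifier total and deterministic. Voxels are classified by their centre
coordinate — no partial-volume weighting — so volumetry is integer voxel
counts times `|det|` of the affine's 3×3 block, and segment volumes sum to
the whole-liver volume bit-exactly. No connected-component clean-up is
applied: the model is plane division, nothing else.

```{r planes}
spec <- phantom_spec()
fit <- couinaud(make_phantom_mask(spec), place_landmarks(spec))
fit$planes
```

## Quantitative maps

cT1 is acquired as 5 axial slices 8 mm thick with a 12 mm gap (20 mm plane
spacing); PDFF as 5 contiguous 20 mm slices. The package aligns these sparse
maps to the labelled volume with a slab model: a voxel centre within
±thickness/2 of a slice plane (closed interval, distance along the slice
normal) takes that slice's nearest in-plane pixel value; gap and
out-of-bounds voxels are missing; overlapping slabs resolve to the nearer
plane, ties to the earlier slice. Nearest-neighbour lookup is deliberate —
medians of quantitative maps should not be computed from interpolated
(invented) values. Alignment assumes the maps and the volume share the
scanner world frame (same-session acquisitions); no registration is
attempted, and breath-hold misalignment is therefore a real-data error source
the package does not model. Per-segment summaries are medians (robust to the
tails that partial slab coverage produces), with segments under `min_voxels`
(default 10) non-missing values flagged rather than reported.

## Resection planning

FLR% = 100 × (total − Σ removed) / total on the nine segment volumes.
"Segment 4" in a plan expands to {4a, 4b}. Adequacy thresholds default to
20% (healthy parenchyma), 30% (steatosis) and 40% (fibrosis/cirrhosis) and
are configuration, not hard-coded clinical advice. A catalogue of canonical
resections (right and extended right hepatectomy, left hepatectomy, left
lateral sectionectomy, segmentectomies) can be enumerated against any
report.

## Agreement statistics

Dice = 2|A∩B|/(|A|+|B|) on identical grids (a grid/affine mismatch is an
error, never a silent 0). Bland–Altman differences are a−b (absolute mode)
or 100(a−b)/((a+b)/2) (percent mode — the pair mean is the standard
denominator for proportional measurements). Bias is the mean difference, the
SD uses n−1, and the 95% limits of agreement are bias ± 1.96 SD (the
conventional multiplier; no small-sample t correction). `simulate_recovery()`
checks the estimator against its analytic Normal limits under a
multiplicative difference model with subject truths drawn uniformly from
1000–2000 mL (typical adult whole-liver volumes).

## The phantom generator

The synthetic phantom is a voxelised ellipsoid — semi-axes (90, 60, 75) mm,
about 1.7 L, at the typical reconstructed resolution 1.2 × 1.2 × 3.0 mm —
with canonically placed landmarks (IVC along a posterior-midline vertical
chord, hepatic-vein and fossa landmarks near the midplane, portal points at
mid-height), optional seeded surface perturbation and landmark jitter,
per-segment constant map values (cT1 750–990 ms in 30 ms steps, PDFF 2–10%)
with seeded Gaussian noise (cT1 SD 50 ms, PDFF SD 1 percentage point), and a
ground-truth volumetry oracle computed by re-evaluating the same geometry on
a 3× supersampled grid. All randomness sits behind explicit integer seeds
and never touches the caller's RNG state.

The phantom is geometric, not anatomically realistic: passing tests
demonstrate correctness of the partition, volumetry, resampling and
statistics on known geometry. They do not demonstrate robustness to the
things real data add — CNN mask errors, lesion exclusion, breath-hold
misalignment between maps and volume, or scanner-dependent boundary
contrast (the known source of between-scanner whole-liver volume bias).

### Numerical choices worth knowing about

* **Half-voxel lattice offset.** The canonical landmarks sit at round world
  coordinates, so an unshifted grid would place entire voxel-centre lattice
  planes exactly on decision planes; the tie rule would then assign whole
  boundary slabs to one side. The phantom grid is offset half a voxel so
  that voxel centres never coincide with a decision plane.
* **Discretisation limits of voxel-centre volumetry.** A transverse portal
  plane falling a fraction into a 3 mm slice cell systematically transfers
  up to half a slice thickness times the plane's cross-sectional area
  between superior/inferior neighbours. For 60–120 mL segments this can
  reach a few percent of segment volume — the dominant error term in the
  package's own volumetry checks, and an intrinsic property of voxel-centre
  counting at 3 mm slices, not of the plane construction.
* **Slab broadcast and median precision.** Each 2D slice pixel serves every
  volume voxel in its slab (~8/3 voxels for cT1), so the effective number of
  independent samples behind a segment median is the pixel count, not the
  voxel count; and a slab that straddles a portal plane mixes the two
  neighbouring segments' values into each other's medians. On the canonical
  phantom the middle cT1 slab straddles the left portal plane (it sits at
  the liver's mid-height), so segment 2/3/4a/4b medians carry a small
  admixture of their partner's constant. Noise-free constants are still
  recovered exactly (the median is a majority vote), but noisy medians are
  not unbiased at the naive sd/√n(voxels) scale. This is a faithful
  consequence of sparse 2D multislice acquisition.
* **Ties and degeneracies.** Zero signed distance is positive everywhere;
  landmark sets that make a plane undefined (targets on the axis) or its
  orientation ambiguous (orientation point on the plane, within 1e-6 mm)
  raise named errors rather than guessing.
* **Problem sizes.** The test-suite phantoms are 20–30 voxels a side with
  jittered landmarks and perturbed surfaces; volumetry and median checks run
  on the full-size default phantom; the supersampled truth uses factor 3
  (0.4 × 0.4 × 1.0 mm).

## Limitations

The mask is an input: liver delineation (CNN or manual) and lesion exclusion
are out of scope. Intersegmental boundaries are planes — real boundaries
follow the hepatic and portal veins and are curved; plane division is the
model, and its agreement with vessel-based anatomy is an empirical question
this package cannot answer from phantoms. Map-to-volume registration is
assumed exact. FLR thresholds are defaults for configuration, not treatment
recommendations.
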