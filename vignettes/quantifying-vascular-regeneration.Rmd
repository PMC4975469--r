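---
title: "Quantifying hepatic vascular regeneration from 3D vascular images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic vascular regeneration from 3D vascular images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livervasc)
```

## The problem

After a 70% partial hepatectomy, a mouse liver regrows most of its mass
within a week. The regrowth has two components that can be measured on
the organ scale: parenchymal growth (liver volume and weight) and
vascular growth (elongation and widening of the portal- and
hepatic-venous trees, plus out-branching of small terminal vessels).
Casting the vasculature with a radiopaque silicone compound and scanning
the explanted organ with micro-CT at isotropic 70 µm resolution yields
3D volumes from which both components can be quantified.

`livervasc` implements that quantification end to end, and — because
animal specimens are not reproducible inputs — pairs it with a synthetic
phantom generator so that every stage can be validated against known
ground truth.

## The processing chain

1. **Segmentation** (`segment_liver`, `segment_vessels`): intensity
   thresholds separate background, soft tissue and contrast-filled
   vessels. The automatic threshold uses Otsu's criterion; because the
   full histogram is trimodal with a small, far-away vessel class that
   dominates the between-class variance, the liver threshold is found by
   a second Otsu below the first split, and the vessel threshold by Otsu
   restricted to the liver interior. The liver mask is pre-smoothed with
   a 3×3×3 box filter (organ masks are otherwise speckled by noise), the
   largest connected component is kept and interior cavities are filled.
   The vessel mask is an exact threshold on raw intensities.
2. **Quality gate** (`check_injection_quality`): a cast is analyzable
   only if intact; the 26-connected component containing the root must
   hold at least 95% of the vessel voxels (the cutoff is a configurable
   reporting parameter — the original criterion is visual).
3. **Skeletonization** (`skeletonize`): six-subiteration border thinning
   deleting only *simple* voxels, characterized by the (26, 6)
   topological numbers T26 = T6 = 1, with curve endpoints preserved.
   Border and endpoint status are frozen at the start of each
   subiteration; this detail matters — re-checking endpoints during
   deletion grows hairs on blunt vessel ends, while re-collecting
   borders mid-pass lets freshly exposed centerlines unzip.
4. **Radii** (`estimate_radii`): the Euclidean distance transform at
   each centerline voxel is the maximal inscribed sphere radius.
   Structures at or below one voxel distance are flagged
   below-resolution and reported as half a voxel.
5. **Graph extraction** (`build_graph`): junction voxels (≥ 3 skeleton
   neighbours) merge into nodes at radius-weighted cluster centroids;
   junction-free runs become polyline edges. Centerline polylines are
   relaxed by a few Laplacian iterations (digital zigzag otherwise
   inflates length by up to ~12%). Imaging-artifact loops are broken at
   the smallest-radius non-bridge edge. Terminal spurs shorter than 3.5
   junction-side radii — the classic thinning artifact on thick vessels —
   are pruned, below-resolution noise twigs are removed, and terminal
   centerlines are extended into the vessel end caps (a medial axis
   retracts from an open end by about one local radius). The vessel mask
   is morphologically closed before thinning: under 26-connectivity a
   sub-voxel background wedge between two daughter branches otherwise
   creates a spurious digital handle at nearly every bifurcation.
6. **Tree model** (`graph_to_tree`): every graph edge becomes one
   straight cylinder (node-to-node centerline, length-weighted mean
   radius). Nodes with more than two branches are split into nested
   bifurcations by ε-length connector edges (ε = spacing/10), pairing
   the two largest-radius children first; with that pairing the
   classical Strahler recursion on the bifurcative tree reproduces the
   generalized multifurcation Strahler rule, so connector edges
   automatically carry their child-side order. Connectors are excluded
   from radius statistics and angle extraction and contribute only their
   negligible ε length to sums.
7. **Territories and virtual resection** (`compute_territories`,
   `virtual_resection`): every liver voxel is assigned the lobe label of
   the nearest cylinder centerline segment (nearest-vessel Voronoi
   decomposition, the standard surgical-planning model; ties go to the
   lexicographically smaller label). Virtual resection removes the
   labeled subtrees — and any supply segment left without a surviving
   terminal branch — then restores strict bifurcation by fusing
   single-child chains (length-weighted radii). An optional stump length
   emulates surgical resection, which leaves vessel stumps that inflate
   the remnant.
8. **Measures** (`measurement_report` and friends): total edge length
   (Σ cylinder lengths), total vascular volume (Σ πr²L, junction
   overlaps and gaps deliberately ignored, as in the cylinder-tree
   simplification), maximal vessel length (root to most distant tip
   along the vessels), path tortuosity (path length over straight-line
   distance), root radius, edge-length density (mm/ml) and vascular
   volume fraction. Lengths are mm, volumes ml (1 ml = 1000 mm³).
   Changes over time are reported as fold increases over an explicit
   reference state and percent recovery relative to normal; the
   one-decimal/integer rounding is a formatting layer
   (`report_fold`, `report_percent`) on top of raw values.

## The isotropic-expansion null model

If regeneration were a uniform magnification with linear factor λ, the
parenchymal volume fold would be f = λ³ and every descriptive parameter
would follow a power of λ: radii and lengths ×λ, vascular volume ×λ³,
edge-length density ×λ⁻², volume fraction ×1, branching angles
unchanged.

Scan resolution does not grow with the organ, so a later scan shows
small vessels that existed earlier below the detection limit. Comparing
raw cumulative parameters would mix growth with visibility. The
*visibility threshold* removes this: under isotropy, an edge with radius
≥ θ = λ·r_min at the later time point already had radius ≥ r_min — and
was therefore visible — earlier. `theta_visible_subtree` prunes the
later tree from the root down to edges above θ (keeping subtree
connectivity; no chain fusion, since straightening a pruned chain would
alter exactly the lengths being compared), and `compare_growth`
contrasts the entire earlier tree with the θ-visible part of the later
one. A parameter is *compatible* with isotropy when its observed fold is
within a stated relative tolerance (default 10%) of the expected fold;
the overall verdict is compatible only if every parameter is. The
tolerance is an explicit, reported parameter: the underlying study
reports a qualitative "differed substantially", so any numeric cutoff is
a choice of this implementation.

Branching-angle similarity is reported alongside: angles are
scale-invariant, so isotropy predicts unchanged distributions. The
similarity is a histogram intersection (18 bins over 0–180°, densities
summing to 1): 1 for identical distributions, 0 for disjoint support.
The original similarity measure is only characterized as a value in
[0, 1]; histogram intersection is this package's concrete instantiation
and is pluggable.

With the published fold changes of the regenerated right inferior lobe
(portal system, postoperative day 7 vs. after virtual resection) the
verdict reproduces the published conclusion:

```{r verdict}
published <- c(radius = 1.4, maximal_vessel_length = 1.3,
               total_edge_length = 2.6, total_vascular_volume = 4.9)
growth_verdict(published, volume_fold = 2.6, tolerance = 0.10)
```

Radius and maximal length are close to λ = 2.6^(1/3) ≈ 1.375, but the
cumulative parameters are roughly twice their isotropic expectation —
growth is concentrated in vessels beyond mere magnification.

## What the phantom generator emulates — and what it does not

`generate_tree` grows a strictly bifurcative tree toward uniformly
sampled target points in an ellipsoidal "liver" domain, recursively
splitting the target set along its principal axis. Radii obey Murray's
law r_p^m = r_1^m + r_2^m (default m = 3) with flow proportional to the
number of downstream tips, which makes the Murray residual zero by
construction and radii monotone from root to tip.

Default study conditions, chosen once for anatomical plausibility:

* domain semi-axes 6.2 × 4.4 × 3.5 mm (≈ 0.40 ml, a remnant-liver/lobe
  scale), voxel spacing 0.07 mm (the scan protocol's resolution);
* root radius 0.35 mm (the measured normal portal in/outflow radius;
  0.47 mm is the hepatic-vein scale), minimum radius 0.07 mm;
* branch length ≈ 6 radii, with a floor of 4.5 radii between successive
  bifurcations; terminal branches at least 10 tip radii long;
* deviation angles from a truncated normal (mean 35°, SD 15°, bounds
  20–80°) and a 30° minimum inter-daughter angle;
* at least 0.25 mm of parenchyma between non-adjacent branches, enforced
  by candidate re-sampling during growth plus a post-hoc relaxation that
  nudges the tree node nearest each residual contact;
* intensities 1000 (vessel) / 100 (tissue) / 0 (background) with
  Gaussian noise of SD 50.

The geometric separation constraints are not cosmetic: distinct vessels
in a real cast are separated by parenchyma, and below ~3 voxels of
separation two casts are one object to any (26-connected) digital
topology. Sub-resolution twigs are likewise not reportable tips at any
scan resolution, hence the terminal length floor.

Growth transforms (`apply_growth`) cover isotropic expansion (the null
model), per-axis anisotropic scaling, radius-only dilation (emulating
pressure-driven distension), terminal outgrowth (new bifurcations with
radii in (0.25, 0.5] of the parent, emulating out-branching of small
vessels crossing the visibility threshold), and ordered compositions.

What the phantoms deliberately do **not** model: hemodynamics,
contrast-agent flow and incomplete filling, beam hardening and other CT
artifacts, curved or tapered vessels, inter-animal variability, and the
portal-hypertension physiology that the real data reflect. Passing
phantom tests therefore demonstrates correctness of the geometry
pipeline under realistic scale, contrast and noise — not robustness to
every pathology of real casts.

## Numerical choices and degenerate inputs

* World coordinates in mm; voxel (0-based) index i maps to world as
  origin + i·spacing; volumes round-trip through NIfTI via the sform.
* Murray residuals are exact to floating point; the acceptance bound is
  1e-9 relative.
* Ties: target splits use a stable order; junction clusters are numbered
  by smallest linear voxel index; territory ties go to the smaller lobe
  label; child pairing at multifurcations is by descending radius with
  original order as tie-break.
* Degenerate inputs: a single-tip request yields one root cylinder;
  empty segmentations warn and return empty masks; a root below the
  visibility threshold warns and returns an empty tree; trees with
  single-child chains (possible after θ-pruning) are accepted by all
  measures, which rely only on parent links.
* Problem sizes: the test-suite and acceptance phantoms use 8–32 tips at
  0.07–0.15 mm spacing (grids up to ≈ 2.6 million voxels) and 16-tip
  ground-truth pairs for growth comparisons; these sizes make every
  stage's behaviour measurable in seconds to a couple of minutes while
  keeping all radii comfortably above the resolution limit.

## Known limitations

* Cylinder trees underestimate lengths by a few percent relative to
  ground truth (straightening plus end-cap retraction); the voxel
  pipeline recovers total edge length to within about 5% on phantoms and
  tip counts and Strahler root orders exactly under the default study
  conditions.
* Radii from the distance transform carry ±1 voxel uncertainty and are
  biased low near junctions and vessel ends; vascular volumes inherit
  this (slight underestimation, a known property of graph pipelines).
* The θ-visibility restriction assumes the isotropic λ when computing θ
  itself; for strongly non-isotropic growth θ is only a first-order
  correction of the visibility artifact.
* Loop breaking assumes loops are artifacts; genuinely anastomosing
  vasculature would need a different graph model.
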