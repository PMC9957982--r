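---
title: "Geometric characterisation and hierarchical labelling of cerebral arterial trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric characterisation and hierarchical labelling of cerebral arterial trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cavlabel)
```

## The problem

Quantitative cerebrovascular research needs every artery in a
time-of-flight MR angiogram named: which voxels are the basilar artery,
which are the right angular branch of the middle cerebral artery, and so
on. Manual labelling is slow and observer-dependent, and the arterial tree
varies substantially between subjects — communicating arteries come and go,
and intracranial atherosclerosis (ICAS) can remove whole territories.
`cavlabel` implements an automated labelling pipeline for binary
(pre-segmented) angiographic volumes: geometric characterisation of the
vessel tree, a hierarchical reframing of the vasculature into **spots,
segments, branches and chunks**, and a two-step neural-network classifier
with segment-wise majority voting and anatomical post-processing. Because
no public labelled MRA cohort accompanies the method, the package also
ships a synthetic Circle-of-Willis simulator that generates labelled
phantom cohorts on which every stage is validated.

## The vascular unit hierarchy

* **Spot** — the atomic unit: a point sampled every 0.2801 mm of arc length
  along the extracted arterial centerline, carrying a 9-dimensional
  geometric feature vector plus its spatial coordinates.
* **Segment** — a contiguous run of spots between bifurcations (or a
  bifurcation and an endpoint); one segment per junction-to-junction
  centerline path.
* **Branch** — one of 62 conventionally named arteries (e.g. the angular
  MCA), identified as `<chunk>.<2-digit index>` (`"A7.06"`); chunks owning
  a single branch use the bare chunk code (`"P0"`, basilar).
* **Chunk** — one of 20 functional-anatomical groupings (`A0`–`A10`
  anterior, `P0`–`P8` posterior; odd numbers right, even left). Chunk-level
  analysis reduces ~5,000 spots to 20 interpretable territories.

The full 62-branch/20-chunk table ships as an editable JSON resource
(`inst/extdata/nomenclature.json`). Published sources name the 20 chunks
and the branch identifier grammar but do not enumerate every chunk's
membership; memberships reconstructed from conventional neurovascular
anatomy are flagged `"provisional": true` in that file, and the file also
carries a chunk-adjacency prior (which chunk pairs may legitimately touch)
used by the post-processing rules. A few branch codes that appear in
figure captions (e.g. `A7.09`) anchored the per-chunk counts.

## Geometry extraction

Input is a binary occupancy grid with voxel spacing (NIfTI-1 via
`read_volume_nifti()`). The stages, each an exported function:

1. **Isovoxel resampling** (`resample_isovoxel()`): anisotropic grids are
   resampled to the smallest axis spacing with cubic (Catmull–Rom)
   greyscale interpolation and re-binarised at 0.5.
2. **Surface extraction** (`extract_surface()`): marching tetrahedra over a
   lightly Gaussian-smoothed occupancy (σ = 1 voxel), padded so every
   component closes. Smoothing removes the staircase bias that would
   otherwise inflate surface area; if a sub-resolution structure would
   vanish under smoothing the binary field is meshed directly.
3. **Skeletonisation** (`skeletonize()`): topology-preserving 3D thinning
   (6-subiteration border peeling with a Bertrand–Malandain simple-point
   re-check at deletion time) to a one-voxel curve skeleton, plus the exact
   Euclidean distance transform (Felzenszwalb–Huttenlocher), whose value at
   a centerline point is the maximally inscribed sphere radius. Redundant
   diagonal edges of the 26-connectivity (triangle shortcuts at path
   corners) are dropped from the skeleton graph so degree classes reflect
   real topology.
4. **Pruning** (`prune_skeleton()`): leaf paths shorter than 2 mm (default,
   configurable — no published value exists) attached to junctions are
   removed to a fixed point; bare trunks are never removed.
5. **Tree construction** (`build_tree()`): one root per component on the
   lowest occupied slice (ties by smallest x, then y); cycles are broken by
   a spanning tree that maximises retained inscribed radius, so cuts fall
   on the thinnest vessels — in a Circle of Willis, the communicating
   arteries.
6. **Centerline extraction** (`extract_centerlines()`): junction-to-junction
   paths, moving-average smoothed (window 5), radius-annotated from the
   distance transform, tangents by central differences. Thinning retracts
   tube tips by roughly one radius; terminal polylines are therefore
   extended along the local tangent to the vessel wall, which restores
   straight-phantom arc length to within 2%.

Centerlines are computed from the thinned skeleton and distance transform
rather than by tracking Voronoi cell boundaries between surface vertices:
the output contract (a radius-annotated centerline) is the same, and the
skeleton route is standard, robust, and directly testable against
phantoms.

## Spot features

`sample_spots()` places spots by arc length (0, d, 2d, …, end point always
included; d = 0.2801 mm). `spot_features()` computes, per spot:

| feature | definition | units |
|---|---|---|
| cross-sectional area | planar section ⊥ tangent, connected region at the spot | mm² |
| inscribed radius | distance transform at the centerline point | mm |
| min/max diameter | caliper chords through the section centroid, 1° steps | mm |
| radius ratio | max/min diameter | – |
| circumference | marching-squares contour length of the section | mm |
| distortion | arc/chord over a centred 5 mm window (one-sided at ends) | ≥ 1 |
| curvature | Menger (circumradius) curvature over a ±2.5 mm window | mm⁻¹ |
| circularity | 4πA/P² (isoperimetric; `4A/P` hydraulic form via config) | (0, 1.05] |

Sections are sampled trilinearly at half-voxel pitch on the perpendicular
plane; the section's area is integrated on a 4× supersample of the same
masked continuous field the perimeter contour is traced on, which keeps
the isoperimetric ratio ≤ 1 up to discretisation (phantom sections stay in
[0.9, 1.006]). "Distortion" and "curvature" have no published formulas;
arc/chord tortuosity and Menger curvature are the field-standard choices
and both are validated against closed forms (straight tube → 1 and 0;
circle of radius R → curvature 1/R).

The classifier consumes 12 predictors: the 9 features plus spot
coordinates. Coordinates are normalised (foreground centre of mass
subtracted, scaled by the foreground bounding-box diagonal) so the
pipeline does not assume co-registered head frames.

## Two-step classification with voting

Step 1 assigns every spot to one of 20 chunks; step 2 assigns spots of
each chunk to that chunk's branches; both use small multilayer
perceptrons. Concretely: `nnet`'s single-hidden-layer MLP (softmax output,
weight decay 5e-4, inverse-frequency class weights, hidden size 48, 350
iterations by default) — a 12-predictor tabular problem does not need a
deeper network, and L2 decay plus an iteration cap stands in for early
stopping, which `nnet` does not expose. The step-1 model is a bag of three
replicates, each trained on its own random subsample (≤ 30k spots) of the
training pool, with averaged softmax outputs; bagging buys 1–2 accuracy
points at bounded cost and `mlp_bag = 1` restores a single net. Step-2
branch models are single nets (their errors do not propagate to chunk
assignments). Training subjects only are used to fit the feature
standardiser. Splits are by subject (never by spot), 70/30, stratified by
cohort.

**Voting**: every spot in a segment adopts the segment's modal predicted
label; ties break by summed predicted probability, then lexicographically.
Voting is applied at chunk level and again at branch level (each
toggleable). Under a two-label confusion model with iid per-spot accuracy
p, voting a 15-spot segment succeeds exactly when ≥ 8 spots are correct —
the binomial tail Σ_{k≥8} C(15,k) p^k (1−p)^{15−k} ≈ 0.950 at p = 0.7 —
and the implementation reproduces this oracle to ±0.01.

**Anatomical post-processing** (`anatomical_postprocess()`): published
descriptions mention rule-assisted complementation without enumerating
rules, so the package ships explicit, config-disableable stand-ins applied
to segment labels until a fixed point (idempotent). Segment adjacency is
exact — segments sharing a skeleton junction node touch (with a
spot-proximity fallback for tables lacking node ids).

* *connectivity* — a segment is a stray island when it has at least two
  adjacent segments, none sharing its chunk, none carrying an anatomically
  adjacent chunk (per the nomenclature's adjacency prior), all unanimous
  about one other chunk, and its own label confidence is low (< 0.75 mean
  posterior). Islands whose *mirror* chunk fits the neighbourhood are side
  errors and flip to the mirror; the rest adopt the neighbours' chunk.
  Each guard exists because its absence misfires: the prior because
  cerebellar arteries (SCA/AICA/PICA) share a chunk yet attach separately
  to the basilar; the two-neighbour minimum because a correct leaf would
  otherwise be relabelled whenever its single neighbour is wrong; the
  confidence gate because confident correct labels next to a mispredicted
  trunk must not cascade.
* *laterality* — right/left chunk pairs must lie on consistent sides of
  the labelled mass's mid-sagittal plane; the rule is scoped to segments
  the adjacency graph cannot adjudicate (no neighbours at all) and flips
  them to the mirror chunk when they sit > 5 mm on the wrong side, with
  the side sign learned from the labelled majority. Midline-hugging
  vessels (pericallosal ACA) legitimately cross the plane, hence the
  conservative scoping. A stronger variant propagating side along the
  tree (`rule_side_propagation`) is available but off by default: measured
  on synthetic cohorts it flips genuinely midline-crossing territories
  more often than it repairs side errors.

Step 2 runs inside the post-processed chunk assignment, so
`chunk_of(pred_branch) == pred_chunk` holds for every spot by
construction.

## The synthetic cohorts

`cow_template()` hard-codes a Circle-of-Willis-like forest: two internal
carotid roots and a basilar root, 62 branches with anatomically plausible
lengths (ICA ~32 mm, pial MCA fans 24–38 mm), calibres (2.3 mm proximal
ICA tapering to 0.6 mm distal pial radii), sinusoidal tortuosity, and
presence probabilities. Communicating arteries are represented as branches
of one side so the structure stays a forest; the anterior communicating
artery (`A0`) is present with probability 0.6, reflecting its reported
instability, and posterior communicating arteries with 0.7. Whole-chunk
dropout (pial PCA/ACA territories, fetal-type P1 variants) gives controls
~18–19 present chunks. `sample_tree()` adds per-subject global scale
(truncated Gaussian, ±12%), per-branch length/radius jitter (±15%),
attachment jitter, orientation jitter, axial head rotation (σ = 3°) and
translation. Template lengths are calibrated so control trees carry on the
order of 4,500–5,000 spots at the 0.2801 mm interval — matching the
reported cohort profile of roughly five thousand spots, ~40 segments and
~18 chunks per control subject. ICAS-like subjects receive 1–3 lesions on
major branches (55% occlusions, which delete the subtree; otherwise
50–85% stenoses over a 5 mm window), lowering expected chunk counts, as in
stroke-with-ICAS cohorts.

What the simulator does **not** emulate: MR signal formation and
flow-related artefacts, segmentation errors of a region grower, cortical
context, and true anatomical shape statistics (variation here is
parametric jitter around one template). Passing tests therefore
demonstrate the pipeline's correctness and its robustness to parametric
anatomy/pathology variation — not clinical performance on real MRA.

Two phantom families back the geometry tests: analytic solids (cylinder,
sphere, Y-tube, torus) with closed-form areas/volumes, and
`sample_topology_tree()` — random trees built with collision rejection so
their tube embedding is a genuine embedded forest. The distinction
matters: in the anatomical template, sibling trunks and the
communicating-artery region *touch by design* (as in real anatomy), which
changes raster topology; topology recovery is therefore validated on the
embedded-forest phantoms, where expected endpoint/junction counts follow
exactly from the specification. Junction counts are compared at the
resolvable scale: junction voxels closer than max(3 voxels, sum of local
radii) merge, and the expectation applies the same rule.

## Numerical choices and problem sizes

* Cohort simulations voxelize at 0.5 mm isotropic; single-phantom
  geometry checks run at 0.28 mm (the native MRA-scale default,
  `voxelize(spacing_mm = 0.284)`). The spot interval stays 0.2801 mm
  throughout — spot counts are set by centerline length, not voxel size.
* The validation experiment uses 30 control subjects (70/30 split ⇒ 21
  train / 9 test) plus 10 ICAS subjects labelled by the control-trained
  ensemble; ~135k labelled spots, of which up to 100k train step 1.
* Ties: voting (probability sum, then code), nearest-label transfer
  (distance, then code), root selection (lowest slice, then x, then y) —
  all deterministic; every stochastic stage derives its stream from one
  root seed.
* Degenerate inputs: empty volumes error; polylines shorter than one spot
  interval yield their two end spots; one-sided windows at polyline ends;
  failed cross-sections (spot off-foreground after smoothing) are dropped
  and logged, never silently imputed.

## Known limitations

* Binary input only: no lumen intensity features, no wall imaging.
* The nomenclature's provisional memberships await an authoritative
  enumeration; edit the JSON to re-map without touching code.
* The laterality rule assumes an approximately vertical mid-sagittal
  plane (axial acquisitions); heavily rotated frames would need a
  plane-fitting step.
* `separability_check()`'s silhouette values are conservative in absolute
  terms — the spectral embedding's second dimension carries within-cluster
  structure, so even perfectly separated class pairs plateau near 0.5.
  Interpret silhouettes comparatively: against the shuffled-label null
  (which sits at 0) and across labelling levels (chunk vs branch).
* Skeleton-based centerlines retract at tube tips (compensated by tip
  extension) and can merge junctions closer than the resolvable scale;
  sub-voxel vessels (radius < half spacing) may vanish — voxelization
  warns when a branch is at risk.
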