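---
title: "Connectivity-driven subdivision of anatomical cortical parcels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-driven subdivision of anatomical cortical parcels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anatomical cortical atlases of the Desikan-Killiany kind label each gyrus as
one parcel, which is far coarser than the organization suggested by
white-matter connectivity: a single gyrus typically hosts the terminations of
several distinct fiber bundles. `cortiparcel` subdivides each anatomical
parcel into *sub-parcels*, each seeded by the cortical footprint of one
bundle extremity and stabilized across a population of subjects. The inputs
are (a) per-subject tractograms (3-D polylines, "fibers"), (b) a bundle
atlas — named bundles of 21-point fibers with a per-bundle maximum
classification distance, a 21-point centroid, and the pair of anatomical
regions the bundle connects — and (c) a triangulated cortical surface with
one anatomical label per vertex, shared (same vertex/triangle indexing) by
all subjects. All geometry is assumed co-registered; registration is out of
scope.

## Pipeline

1. **Bundle segmentation.** A fiber `f` (resampled to 21 equidistant points)
   is compared with every atlas fiber `a` by the maximum
   corresponding-point distance `d(f, a) = max_k ||f_k − a_k||`, evaluated in
   both orientations (about half of tractography fibers are stored reversed)
   and taking the smaller. `f` is claimed by the bundle containing its
   closest atlas fiber, among the bundles whose threshold it satisfies; ties
   between bundles break by name. Fibers failing every threshold stay
   unlabeled. The vectorized implementation is checked against an exhaustive
   per-pair oracle in the test suite.
2. **Mesh intersection.** Each fiber extremity is resolved to one triangle:
   first a Möller–Trumbore ray cast from the penultimate point through the
   endpoint (accepted if the hit lies at most `ray_epsilon_mm` beyond the
   endpoint), then, failing that, the nearest triangle by point-to-triangle
   distance. Only triangles whose bounding box lies within
   `search_radius_mm` of the endpoint are considered, via a uniform grid
   over triangle AABBs whose query covers the whole search box (so the
   acceleration is exact). Fibers with an unresolved end are dropped and
   counted.
3. **Filtering and alignment.** A fiber survives iff the unordered pair of
   anatomical labels of its end triangles equals the unordered region pair
   of its bundle (intra-region bundles need both ends inside the region).
   Unordered matching is required because fiber orientation is unknown
   before alignment. Survivors are oriented along the bundle centroid: if
   the reversed fiber is closer (same max-corresponding-point metric), point
   order and end triangles are swapped.
4. **Parcellation.** Every bundle seeds two preliminary sub-parcels, one per
   extremity. Across subjects, each surviving fiber adds one count to its
   end triangle and to every triangle sharing a vertex with it; counts
   landing outside the sub-parcel's anatomical region are discarded, so
   sub-parcels always respect the coarse parcellation. Per-triangle counts
   normalize to probabilities (`p = N_i / Σ`, sorted descending, ties by
   label). Sub-parcels smaller than `size_thr` times the region's mean
   sub-parcel support are removed and probabilities recomputed. The *density
   center* of a sub-parcel is the triangle set where its probability reaches
   `dc_thr`; for each region, sub-parcel pairs whose density-center overlap
   `idc = |dc_i ∩ dc_j| / min(|dc_i|, |dc_j|)` reaches `idc_thr` become
   edges of a merge graph. All maximal cliques (igraph's Bron–Kerbosch
   family enumeration, re-ordered deterministically by size then member
   labels) are consumed greedily: a clique fuses whichever of its members
   earlier cliques have not consumed, if at least two remain. After a final
   probability recomputation, the *hard parcellation* assigns each triangle
   its most probable label; count-free triangles stay unlabeled.
5. **Post-processing.** Per sub-parcel, only the largest edge-connected
   component is kept; triangles of smaller components take their
   second-most-probable label when it also occurs among their
   edge-neighbors, otherwise they become unlabeled. A morphological opening
   (one synchronous erosion, then one synchronous dilation with
   majority/lowest-label tie-break) removes isolated speckles.
6. **Evaluation.** Per subject, a binary sub-parcel connectivity matrix is
   built from the whole tractogram; reproducibility is the mean Dice
   coefficient over all subject pairs, where a matrix's set is its nonzero
   upper-triangle cells (diagonal included — intra-parcel connections are
   not excluded, and symmetry would otherwise double-count). Parcellations
   are compared parcel-by-parcel with Dice over triangle sets, best matches
   binned over [0.5, 0.9). The coefficient of variation of per-subject fiber
   counts uses the population standard deviation (the definition σ/μ fixes
   no sample correction). A volumetric label image can be mapped to the
   mesh by nearest labeled voxel center (ties to the lowest voxel index).

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `size_thr` | minimum sub-parcel size, fraction of the region's mean sub-parcel support | 0.10 | conservative: removes only clearly undersized seeds |
| `dc_thr` | minimum probability for density-center membership | 0.15 | keeps centers focused without emptying small sub-parcels |
| `idc_thr` | minimum normalized density-center overlap to merge | 0.10 | merges only clearly co-located seeds |
| `ray_epsilon_mm` | allowed ray overshoot past the endpoint | 2 mm | endpoint may sit slightly short of the surface |
| `search_radius_mm` | candidate-triangle search radius | 3 mm | a few times the endpoint noise scale |

Raising `dc_thr` shrinks density centers and raising `idc_thr` demands more
overlap, so both reduce merging and increase the final sub-parcel count —
the monotone trend asserted by acceptance criterion 7. `size_thr` has an
alternative reading (fraction of the region's triangle count); both are
implemented, `size_mode = "region_mean"` is the default.

## The synthetic cohort

`simulate_cohort()` builds the fully controlled world the test suite runs
in: an icosphere "cortex" (subdivision 4 → 5,120 triangles; radius 100 mm,
hemisphere scale) partitioned into 8 edge-connected regions by nearest
random unit vectors; 2–4 ground-truth footprints per region; one jittered
copy of every atlas fiber per subject (i.i.d. Gaussian point noise,
σ = 0.5 mm), reversed with probability 0.5; plus 20% distractor fibers
rejection-sampled to stay farther than every bundle threshold (plus 1 mm)
from every atlas fiber in either orientation.

Design choices that matter for interpreting green tests:

* **Footprint geometry.** Each region is split into per-footprint clusters
  (BFS from farthest-point seeds). The *sampling core* is the cluster eroded
  by two vertex-rings; the ground-truth footprint is the core dilated back
  by one ring — exactly the support the accumulation rule produces in the
  noise-free limit. Because cores sit two rings inside their cluster,
  σ = 0.5 mm jitter cannot push support across cluster seams, so disjoint
  footprints stay disjoint in probability space and exact-count recovery is
  a meaningful test.
* **Endpoints at triangle barycenters.** Atlas fibers end at the barycenters
  of core triangles, cycled in shuffled order so every core triangle is
  covered when `fibers_per_bundle` (default 64) is at least the core size.
  Barycentric placement keeps endpoints about one triangle inradius
  (≈ 1.6 mm ≈ 3σ) away from edges, so jitter almost never relocates an
  endpoint into a neighboring triangle and the realized support matches the
  ground-truth footprint. With uniform in-triangle sampling ~25% of
  endpoints sit within one σ of an edge and support grows a stochastic
  one-ring halo; that design measured a recovery ceiling of Dice ≈ 0.84
  regardless of pipeline correctness, which is why it was rejected.
* **Bundle thresholds.** The default per-bundle threshold is 6 mm, the
  scale published SWM/DWM atlases use. A threshold of 3σ = 1.5 mm would be
  internally inconsistent with near-total recovery: the maximum over 21
  i.i.d. 3-D Gaussian point offsets exceeds 3σ with probability
  ≈ 1 − P(χ²₃ ≤ 9)²¹ ≈ 0.46, so roughly half of all fibers would be
  rejected; the 99th percentile of that maximum is ≈ 4.3σ.
* **Fiber geometry.** Fibers are spherical-interpolation arcs dipping into
  the sphere interior (white matter lies under the cortical sheet), so only
  the extremities touch the mesh. Distractors are arcs deep inside the
  sphere (radii 0.25–0.35 R).
* **What the sphere does not emulate:** cortical folding, partial-volume
  and tractography-specific error modes (truncated or kinked streamlines),
  per-subject mesh geometry differences (an optional stressor, off by
  default), and realistic fiber counts (~10⁶ per subject). All pipeline
  logic is topology- and label-driven, so folding adds no test power; a
  green suite establishes algorithmic correctness and recovery under the
  stated noise model, not clinical validity.

## Numerical choices

* Möller–Trumbore uses a 1e-12 determinant cutoff and 1e-9 barycentric
  slack; directions are normalized so the ray parameter is in mm.
* Segmentation cross-distances are computed from per-coordinate differences
  rather than the `|x|² + |y|² − 2x·y` expansion, whose cancellation error
  (≈ 1e-6 mm at brain-scale coordinates) breaks exact-match distances.
* All orderings that affect output are total: bundles sort by name,
  sub-parcel labels are assigned in sorted-bundle order (start before end),
  probability ties break label-ascending, cliques order by size then
  lexicographic member labels, component ties by smallest triangle index,
  dilation ties by lowest label. Runs are bit-reproducible at fixed seed.
* Erosion/dilation are synchronous two-phase passes; sequential in-place
  updates would make the result depend on triangle visiting order.
* Components and morphology use edge adjacency (≤ 3 neighbors) so
  single-vertex pinches cannot bridge parcels; probability accumulation
  uses vertex adjacency, per the neighborhood definition.

## Open design points, resolved

* A triangle's region label is the majority of its three vertex labels,
  ties to the lowest-index vertex — the source method labels vertices only,
  but filtering and region-restricted merging need a triangle rule.
* Segmentation assigns by closest member fiber (single linkage), not bundle
  average; orientation is handled at segmentation time rather than deferred.
* Greedy clique consumption skips already-merged members and fuses the
  remainder only if at least two survive; overlap resolution between
  cliques is otherwise undefined in the source method.
* The post-processing "three morphological operations" are implemented as
  the two described procedures (component removal; opening = erosion +
  dilation).

## Known limitations

* Opening can in principle split a dumbbell-shaped sub-parcel into two
  components after the single-component pass; on blob-like sub-parcels (the
  synthetic world and the intended anatomical use) this does not occur, and
  the acceptance suite asserts single-componentness after full
  post-processing.
* The uniform-grid index is built per surface and queried per endpoint in
  interpreted R; for 10⁶-fiber tractograms a compiled spatial index would
  be the first optimization target.
* `read_trk()` refuses voxel-scaled TRK files rather than resampling them;
  registration and voxel-space handling are out of scope.
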