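# cortiparcel

Fine-grained, connectivity-defined subdivision of anatomical cortical
parcels from diffusion-MRI tractography and a fiber-bundle atlas.

## What it does, and for whom

Anatomical cortical atlases (Desikan-Killiany style) label whole gyri. For
structural-connectivity studies that is too coarse: each gyrus hosts the
cortical terminations of several distinct white-matter bundles.
`cortiparcel` is for researchers who have (a) per-subject whole-brain
tractograms, (b) a bundle atlas of 21-point fibers with per-bundle distance
thresholds and region annotations, and (c) a labeled, shared-topology
cortical mesh — and who want each anatomical parcel split into the stable,
bundle-seeded **sub-parcels** supported by their cohort.

The pipeline:

1. **Segmentation** — each fiber `f` is labeled with the bundle of its
   closest atlas fiber under the orientation-aware maximum
   corresponding-point distance, `d(f,a) = min(max_k ||f_k − a_k||,
   max_k ||f_k − a_{22−k}||)`, subject to the per-bundle threshold.
2. **Mesh intersection** — each fiber extremity resolves to one triangle
   (Möller–Trumbore ray cast with a nearest-triangle fallback, exact
   uniform-grid acceleration).
3. **Filtering + alignment** — fibers whose end-triangle labels contradict
   their bundle's region pair are removed; survivors are oriented along the
   bundle centroid.
4. **Parcellation** — each bundle extremity seeds a sub-parcel; fiber-end
   counts spread over the one-vertex-ring neighborhood (clipped at region
   boundaries) and accumulate across subjects into per-triangle probability
   maps `p(SP|t) = N_t / Σ_t`. Small sub-parcels are removed
   (`size_thr`); density centers `{t : p ≥ dc_thr}` are intersected,
   `idc = |dc_i ∩ dc_j| / min(|dc_i|,|dc_j|)`; pairs with
   `idc ≥ idc_thr` form a merge graph whose maximal cliques are fused
   greedily. The hard parcellation takes each triangle's most probable
   label.
5. **Post-processing** — non-largest connected components are reassigned to
   their second label (or unlabeled), then a morphological opening removes
   speckles.
6. **Evaluation** — binary sub-parcel connectivity matrices per subject,
   pairwise matrix Dice (`DSC = 2|A∩B|/(|A|+|B|)`), parcellation-to-
   parcellation Dice tables, and the coefficient of variation `σ/μ` of
   per-subject fiber counts.

A fully controlled synthetic-cohort generator (`simulate_cohort()`) —
labeled icosphere cortex, synthetic bundle atlas with ground-truth
footprints, jittered/flipped/distractor-laden subject tractograms — makes
the whole pipeline testable without any external data.

## Worked example

```r
library(cortiparcel)
cohort <- simulate_cohort(n_subjects = 4, subdivisions = 3, n_regions = 6,
                          footprints_per_region = 2, fibers_per_bundle = 24,
                          seed = 42)
res <- run_pipeline(cohort, pipeline_config())
print(res$parcellation)
print(res$manifest$stage_counts)
print(subparcels_per_region(res$parcellation))
cat(sprintf("mean pairwise connectivity Dice: %.3f\n",
            res$evaluation$pairwise_dice$mean))
```

prints

```
hard_parcellation: 8 sub-parcels, 497/1280 triangles labeled
            preliminary              candidates                  merges
                      8                       8                       0
                  final final_labeled_triangles    surviving_subparcels
                      8                     497                       8
R1 R2 R3 R4 R5 R6
 2  2  1  1  1  1
mean pairwise connectivity Dice: 1.000
```

Reading: the 4-bundle synthetic atlas seeds 8 preliminary sub-parcels (two
per bundle, one per extremity); none fall below the size threshold, none of
the disjoint ground-truth footprints overlap enough to merge, so 8 final
sub-parcels survive, covering 497 of the 1,280 mesh triangles (regions
R1/R2 received two bundle extremities each, R3–R6 one each; the odd ninth
footprint is unused by any bundle). The per-subject connectivity matrices
are identical across these low-noise subjects, so the mean pairwise Dice is
1.000. With a larger cohort and more noise, merges become nonzero when
density centers co-locate, and the Dice drops below 1 with inter-subject
variability.

A command-line driver mirrors the stages
(`inst/exec/cortiparcel {simulate, segment, intersect, filter, run-all}`),
with TSV interfaces between stages.

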