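## End-to-end pipeline orchestration.
##
## Stage order follows the method: (1) bundle segmentation, (3) mesh
## intersection, (4) filtering + alignment, (5) parcellation, (6)
## post-processing, then evaluation. (Step 2, mesh and label extraction, is
## an input contract here: the labeled surface arrives ready-made.) Every
## stage is also independently callable; run_pipeline() wires them together
## and keeps a manifest whose counts must reconcile (filtered <= intersected
## <= segmented).

#' Run the full parcellation pipeline over a cohort
#'
#' @param cohort A `synthetic_cohort` (or any list with `surface` — a
#'   [labeled_surface()] —, `atlas` — a [bundle_atlas()] — and `tractograms`
#'   — a list of 21-point [tractogram()]s sharing the surface's space).
#' @param cfg A [pipeline_config()].
#' @param evaluate Also build per-subject connectivity matrices and their
#'   pairwise Dice (default TRUE).
#' @return List with `parcellation` (post-processed `hard_parcellation`),
#'   `raw_parcellation` (before Step 6), `pmap`, `sps`, `per_subject`
#'   (segmented / intersected / filtered tables), `evaluation` (connectivity
#'   matrices, mean pairwise Dice, coefficient of variation of per-subject
#'   segmented-fiber counts), and `manifest`.
#' @export
run_pipeline <- function(cohort, cfg = pipeline_config(), evaluate = TRUE) {
  surface <- cohort$surface
  atlas <- cohort$atlas
  tracts <- cohort$tractograms
  if (is.null(surface) || is.null(atlas) || !length(tracts))
    cp_stop("cohort must provide surface, atlas and tractograms")
  grid <- build_triangle_grid(surface)
  per_subject <- vector("list", length(tracts))
  filtered <- vector("list", length(tracts))
  counts <- data.frame(subject = seq_along(tracts), fibers = NA_integer_,
                       segmented = NA_integer_, intersected = NA_integer_,
                       filtered = NA_integer_)
  for (s in seq_along(tracts)) {
    t <- tracts[[s]]
    seg <- tryCatch(segment_tractogram(t, atlas),
                    error = function(e) cp_stop(
                      "stage segment failed for subject %d: %s", s,
                      conditionMessage(e)))
    ints <- tryCatch(suppressMessages(
      intersect_tractogram(t, seg, surface, cfg, grid)),
      error = function(e) cp_stop(
        "stage intersect failed for subject %d: %s", s, conditionMessage(e)))
    filt <- tryCatch(filter_tractogram(t, ints, atlas, surface),
                     error = function(e) cp_stop(
                       "stage filter failed for subject %d: %s", s,
                       conditionMessage(e)))
    counts$fibers[s] <- length(t)
    counts$segmented[s] <- nrow(seg)
    counts$intersected[s] <- nrow(ints)
    counts$filtered[s] <- nrow(filt)
    per_subject[[s]] <- list(segmented = seg, intersected = ints,
                             filtered = filt)
    filtered[[s]] <- filt
  }
  par <- tryCatch(parcellate(filtered, atlas, surface, cfg),
                  error = function(e) cp_stop("stage parcellate failed: %s",
                                              conditionMessage(e)))
  post <- tryCatch(postprocess_parcellation(par$parcellation, par$pmap,
                                            surface),
                   error = function(e) cp_stop("stage postprocess failed: %s",
                                               conditionMessage(e)))
  evaluation <- NULL
  if (evaluate) {
    mats <- lapply(tracts, build_connectivity_matrix, parc = post,
                   surface = surface, cfg = cfg, grid = grid)
    pw <- if (length(mats) >= 2L) pairwise_matrix_dice(mats) else NULL
    evaluation <- list(connectivity = mats,
                       pairwise_dice = pw,
                       cv_fiber_count = if (mean(counts$segmented) > 0)
                         coefficient_of_variation(counts$segmented) else NA_real_)
  }
  manifest <- build_manifest(cfg, counts, par, post)
  list(parcellation = post, raw_parcellation = par$parcellation,
       pmap = par$pmap, sps = par$sps, merges = par$merges,
       per_subject = per_subject, evaluation = evaluation,
       manifest = manifest)
}

# Manifest with reconcilable stage counts and content checksums; rerunning
# with an identical cohort/config reproduces it exactly.
build_manifest <- function(cfg, counts, par, post) {
  stopifnot(all(counts$filtered <= counts$intersected),
            all(counts$intersected <= counts$segmented),
            all(counts$segmented <= counts$fibers))
  list(
    config = unclass(cfg),
    subjects = counts,
    stage_counts = c(par$counts,
                     final_labeled_triangles = sum(!is.na(post$labels)),
                     surviving_subparcels = sum(post$label_table$n_triangles > 0)),
    checksums = list(
      label_sum = sum(post$labels, na.rm = TRUE),
      label_table = paste(post$label_table$label,
                          post$label_table$n_triangles,
                          sep = ":", collapse = ",")
    )
  )
}

#' Sub-parcel counts per anatomical region of a parcellation
#'
#' Counts sub-parcels with nonzero triangle support, grouped by region.
#'
#' @param parc A `hard_parcellation`.
#' @return Named integer vector (region code -> count).
#' @export
subparcels_per_region <- function(parc) {
  tab <- parc$label_table
  tab <- tab[tab$n_triangles > 0L, , drop = FALSE]
  out <- table(tab$region)
  stats::setNames(as.integer(out), names(out))
}
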