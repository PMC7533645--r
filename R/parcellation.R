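## Step 5 — cortex parcellation.
##
## Every atlas bundle seeds two preliminary sub-parcels, one per extremity.
## Across all subjects, each surviving fiber adds one count to its end
## triangle and to every triangle of that triangle's vertex-neighborhood,
## clipped at anatomical-region boundaries. Per-triangle counts are
## normalized into probability maps; small sub-parcels are removed; density
## centers (triangles with probability >= dc_thr) are intersected pairwise
## (idc = |dc_i n dc_j| / min sizes) within each anatomical region; pairs
## with idc >= idc_thr form a merge graph whose maximal cliques are fused
## greedily by descending size; the final hard parcellation takes each
## triangle's most probable label.

## ---- sub-parcel container -------------------------------------------------

new_subparcel <- function(label, name, region, tris, counts) {
  o <- order(tris)
  list(label = as.integer(label), name = name, region = region,
       tris = as.integer(tris[o]), counts = as.numeric(counts[o]))
}

subparcel_set <- function(subparcels, n_triangles) {
  labels <- vapply(subparcels, function(s) s$label, 1L)
  subparcels <- subparcels[order(labels)]
  names(subparcels) <- sort(labels)
  structure(list(subparcels = subparcels, n_triangles = n_triangles),
            class = "subparcel_set")
}

#' @export
print.subparcel_set <- function(x, ...) {
  cat(sprintf("subparcel_set: %d sub-parcels over %d triangles\n",
              length(x$subparcels), x$n_triangles))
  invisible(x)
}

#' Build preliminary sub-parcels from filtered fibers
#'
#' Two sub-parcels per atlas bundle (`<name>.start`, `<name>.end`), with
#' labels assigned in sorted-bundle-name order so runs are reproducible. For
#' every subject, each aligned fiber contributes one count to its end
#' triangle and to every triangle sharing a vertex with it; contributions
#' landing on triangles of a different anatomical region are discarded, so
#' sub-parcels always respect the coarse parcellation.
#'
#' @param filtered_by_subject List (one element per subject) of aligned record
#'   data frames from [filter_tractogram()].
#' @param atlas A [bundle_atlas()].
#' @param surface A [labeled_surface()].
#' @return A `subparcel_set`. Sub-parcels with empty support are dropped.
#' @export
build_preliminary_subparcels <- function(filtered_by_subject, atlas, surface) {
  all_recs <- do.call(rbind, filtered_by_subject)
  ntri <- nrow(surface$triangles)
  tri_labels <- surface$triangle_labels
  sps <- list()
  bundle_names <- names(atlas$bundles)
  for (b in seq_along(bundle_names)) {
    bn <- bundle_names[b]
    bun <- atlas$bundles[[bn]]
    recs <- all_recs[all_recs$bundle == bn, , drop = FALSE]
    for (side in c("start", "end")) {
      region <- if (side == "start") bun$region_start else bun$region_end
      rlab <- region_label(surface, region)
      label <- 2L * (b - 1L) + if (side == "start") 1L else 2L
      counts <- numeric(ntri)
      end_tris <- if (side == "start") recs$tri_start else recs$tri_end
      if (length(end_tris)) {
        tab <- table(end_tris)
        for (j in seq_along(tab)) {
          tri <- as.integer(names(tab)[j])
          nb <- c(tri, surface$vertex_adj[[tri]])
          nb <- nb[tri_labels[nb] == rlab]
          counts[nb] <- counts[nb] + as.numeric(tab[j])
        }
      }
      support <- which(counts > 0)
      if (length(support))
        sps[[length(sps) + 1L]] <- new_subparcel(
          label, paste0(bn, ".", side), region, support, counts[support])
    }
  }
  subparcel_set(sps, ntri)
}

## ---- probability maps -----------------------------------------------------

#' Compute per-triangle probability maps over a sub-parcel set
#'
#' For each triangle with any counts, `p(SP | t) = N / sum(N)` over the
#' sub-parcels supporting `t`; lists are sorted by probability descending,
#' ties broken by label ascending. Triangles with no counts are absent.
#'
#' @param sps A `subparcel_set`.
#' @return A `probability_map`: named list keyed by triangle index, each
#'   element holding `labels`, `p`, `counts`.
#' @export
compute_probability_maps <- function(sps) {
  if (!length(sps$subparcels)) cp_stop("no sub-parcels with nonzero support")
  tri <- unlist(lapply(sps$subparcels, function(s) s$tris), use.names = FALSE)
  lab <- rep(unname(vapply(sps$subparcels, function(s) s$label, 1L)),
             vapply(sps$subparcels, function(s) length(s$tris), 1L))
  cnt <- unlist(lapply(sps$subparcels, function(s) s$counts), use.names = FALSE)
  o <- order(tri, lab)
  tri <- tri[o]; lab <- lab[o]; cnt <- cnt[o]
  idx <- split(seq_along(tri), tri)
  pmap <- lapply(idx, function(i) {
    p <- cnt[i] / sum(cnt[i])
    o2 <- order(-p, lab[i])                     # desc p, ties label asc
    list(labels = lab[i][o2], p = p[o2], counts = cnt[i][o2])
  })
  structure(pmap, class = "probability_map", n_triangles = sps$n_triangles)
}

#' Remove small preliminary sub-parcels
#'
#' Within each anatomical region, drops sub-parcels whose support-triangle
#' count falls below `size_thr` times the region's mean sub-parcel support
#' (`size_mode = "region_mean"`, default) or `size_thr` times the region's
#' triangle count (`size_mode = "region_fraction"`).
#'
#' @param sps A `subparcel_set`.
#' @param surface A [labeled_surface()].
#' @param size_thr Fraction in (0, 1).
#' @param size_mode See [pipeline_config()].
#' @return The surviving `subparcel_set` (labels preserved).
#' @export
remove_small_subparcels <- function(sps, surface, size_thr,
                                    size_mode = c("region_mean",
                                                  "region_fraction")) {
  size_mode <- match.arg(size_mode)
  regions <- vapply(sps$subparcels, function(s) s$region, "")
  sizes <- vapply(sps$subparcels, function(s) length(s$tris), 1L)
  keep <- rep(TRUE, length(sizes))
  for (rg in unique(regions)) {
    in_rg <- regions == rg
    ref <- if (size_mode == "region_mean") mean(sizes[in_rg])
    else sum(surface$triangle_labels == region_label(surface, rg))
    keep[in_rg] <- sizes[in_rg] >= size_thr * ref
  }
  subparcel_set(sps$subparcels[keep], sps$n_triangles)
}

## ---- density centers and merging ------------------------------------------

#' Compute density centers
#'
#' The density center of a sub-parcel is the set of triangles where its
#' probability is at least `dc_thr`; it may be empty or disconnected.
#'
#' @param pmap A `probability_map`.
#' @param dc_thr Probability threshold in (0, 1).
#' @param labels Sub-parcel labels to report (default: all present).
#' @return Named list (by label) of integer triangle vectors.
#' @export
compute_density_centers <- function(pmap, dc_thr, labels = NULL) {
  tri_ids <- as.integer(names(pmap))
  lab_all <- unlist(lapply(pmap, function(e) e$labels), use.names = FALSE)
  tri_all <- rep(tri_ids, vapply(pmap, function(e) length(e$labels), 1L))
  p_all <- unlist(lapply(pmap, function(e) e$p), use.names = FALSE)
  sel <- p_all >= dc_thr
  dcs <- split(tri_all[sel], lab_all[sel])
  if (is.null(labels))
    labels <- sort(unique(lab_all))
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (l in as.character(labels))
    out[[l]] <- sort(unique(dcs[[l]] %||% integer()))
  out
}

#' Normalized density-center overlap (idc)
#'
#' `|dc_i n dc_j| / min(|dc_i|, |dc_j|)`; defined as 0 when either set is
#' empty.
#'
#' @param dc_i,dc_j Integer triangle sets.
#' @return A fraction in \[0, 1\].
#' @export
compute_idc <- function(dc_i, dc_j) {
  if (!length(dc_i) || !length(dc_j)) return(0)
  length(intersect(dc_i, dc_j)) / min(length(dc_i), length(dc_j))
}

#' Build the merge graph of one anatomical region
#'
#' Vertices are the region's candidate sub-parcels; an edge joins two
#' sub-parcels when their density-center overlap reaches `idc_thr`
#' (inclusive). Isolated sub-parcels are excluded — they bypass merging.
#'
#' @param labels Integer labels of the region's candidate sub-parcels.
#' @param dcs Density centers from [compute_density_centers()].
#' @param idc_thr Threshold in (0, 1).
#' @return A `merge_graph`: list with `vertices` (labels) and `edges`
#'   (two-column label matrix).
#' @export
build_merge_graph <- function(labels, dcs, idc_thr) {
  labels <- sort(as.integer(labels))
  edges <- matrix(integer(), 0L, 2L)
  if (length(labels) >= 2L) {
    pairs <- utils::combn(labels, 2L)
    hit <- apply(pairs, 2L, function(pr)
      compute_idc(dcs[[as.character(pr[1L])]], dcs[[as.character(pr[2L])]]) >=
        idc_thr)
    edges <- t(pairs[, hit, drop = FALSE])
  }
  vertices <- sort(unique(as.integer(edges)))
  structure(list(vertices = vertices, edges = edges), class = "merge_graph")
}

#' Enumerate maximal cliques of a merge graph
#'
#' Backed by igraph's maximal-clique enumeration; the result is ordered by
#' clique size descending, ties broken lexicographically on the sorted member
#' labels, so the subsequent greedy merge is deterministic.
#'
#' @param g A `merge_graph`.
#' @return List of integer label vectors (each sorted ascending).
#' @export
enumerate_maximal_cliques <- function(g) {
  if (!length(g$vertices)) return(list())
  ig <- igraph::graph_from_edgelist(
    matrix(as.character(g$edges), ncol = 2L), directed = FALSE)
  cl <- igraph::max_cliques(ig)
  cl <- lapply(cl, function(v) sort(as.integer(igraph::V(ig)$name[v])))
  sizes <- vapply(cl, length, 1L)
  key <- vapply(cl, function(v) paste(sprintf("%09d", v), collapse = ""), "")
  cl[order(-sizes, key)]
}

#' Merge candidate sub-parcels by maximal cliques
#'
#' Greedy pass over size-sorted cliques: a clique fuses all of its members
#' that have not been consumed by an earlier clique, provided at least two
#' remain. Fused sub-parcels sum their per-triangle counts, concatenate their
#' names, and receive fresh labels past the current maximum.
#'
#' @param sps A `subparcel_set` (the candidates plus any non-candidates).
#' @param cliques Output of [enumerate_maximal_cliques()] (possibly from
#'   several regional graphs, concatenated).
#' @return List with `sps` (the merged `subparcel_set`) and `merges` (data
#'   frame logging each fusion: `new_label`, `members`, `name`).
#' @export
merge_cliques <- function(sps, cliques) {
  consumed <- integer()
  next_label <- if (length(sps$subparcels))
    max(vapply(sps$subparcels, function(s) s$label, 1L)) + 1L else 1L
  merged <- list()
  log <- list()
  for (cl in cliques) {
    avail <- setdiff(cl, consumed)
    if (length(avail) < 2L) next
    members <- sps$subparcels[as.character(avail)]
    counts <- numeric(sps$n_triangles)
    for (m in members) counts[m$tris] <- counts[m$tris] + m$counts
    support <- which(counts > 0)
    nm <- paste(vapply(members, function(m) m$name, ""), collapse = "+")
    merged[[length(merged) + 1L]] <- new_subparcel(
      next_label, nm, members[[1L]]$region, support, counts[support])
    log[[length(log) + 1L]] <- data.frame(
      new_label = next_label, members = paste(avail, collapse = ","),
      name = nm, stringsAsFactors = FALSE)
    consumed <- c(consumed, avail)
    next_label <- next_label + 1L
  }
  survivors <- sps$subparcels[!vapply(sps$subparcels,
                                      function(s) s$label %in% consumed, TRUE)]
  list(sps = subparcel_set(c(survivors, merged), sps$n_triangles),
       merges = if (length(log)) do.call(rbind, log)
       else data.frame(new_label = integer(), members = character(),
                       name = character(), stringsAsFactors = FALSE))
}

## ---- hard parcellation ----------------------------------------------------

#' Harden a probability map into one label per triangle
#'
#' Each triangle with any counts takes the top label of its sorted
#' probability list (ties already resolved label-ascending by the sort);
#' triangles without counts stay unlabeled (`NA`).
#'
#' @param pmap A `probability_map` recomputed over the final sub-parcels.
#' @param sps The final `subparcel_set` (for the label table).
#' @return A `hard_parcellation`: list with `labels` (integer vector, `NA`
#'   for unlabeled triangles) and `label_table` (`label`, `name`, `region`,
#'   `n_triangles`).
#' @export
harden <- function(pmap, sps) {
  ntri <- attr(pmap, "n_triangles")
  labels <- rep(NA_integer_, ntri)
  tri_ids <- as.integer(names(pmap))
  labels[tri_ids] <- vapply(pmap, function(e) e$labels[1L], 1L)
  tab <- data.frame(
    label = vapply(sps$subparcels, function(s) s$label, 1L),
    name = vapply(sps$subparcels, function(s) s$name, ""),
    region = vapply(sps$subparcels, function(s) s$region, ""),
    stringsAsFactors = FALSE)
  tab$n_triangles <- vapply(tab$label, function(l) sum(labels == l, na.rm = TRUE), 1L)
  rownames(tab) <- NULL
  structure(list(labels = labels, label_table = tab),
            class = "hard_parcellation")
}

#' @export
print.hard_parcellation <- function(x, ...) {
  cat(sprintf("hard_parcellation: %d sub-parcels, %d/%d triangles labeled\n",
              sum(x$label_table$n_triangles > 0), sum(!is.na(x$labels)),
              length(x$labels)))
  invisible(x)
}

#' Run the full parcellation step over filtered records
#'
#' Chains [build_preliminary_subparcels()], size filtering, density-center
#' overlap analysis per anatomical region, clique merging, and [harden()].
#'
#' @inheritParams build_preliminary_subparcels
#' @param cfg A [pipeline_config()].
#' @return List with `parcellation` (a `hard_parcellation`), `pmap`, `sps`
#'   (final sub-parcels), `merges` log, and stage counts.
#' @export
parcellate <- function(filtered_by_subject, atlas, surface, cfg) {
  prelim <- build_preliminary_subparcels(filtered_by_subject, atlas, surface)
  pmap <- compute_probability_maps(prelim)
  cand <- remove_small_subparcels(prelim, surface, cfg$size_thr, cfg$size_mode)
  pmap <- compute_probability_maps(cand)
  dcs <- compute_density_centers(pmap, cfg$dc_thr)
  regions <- vapply(cand$subparcels, function(s) s$region, "")
  cliques <- list()
  for (rg in sort(unique(regions))) {
    labs <- vapply(cand$subparcels[regions == rg], function(s) s$label, 1L)
    g <- build_merge_graph(labs, dcs, cfg$idc_thr)
    cliques <- c(cliques, enumerate_maximal_cliques(g))
  }
  mg <- merge_cliques(cand, cliques)
  pmap <- compute_probability_maps(mg$sps)
  parc <- harden(pmap, mg$sps)
  list(parcellation = parc, pmap = pmap, sps = mg$sps, merges = mg$merges,
       counts = c(preliminary = length(prelim$subparcels),
                  candidates = length(cand$subparcels),
                  merges = nrow(mg$merges),
                  final = length(mg$sps$subparcels)))
}
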