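## Step 6 — morphological post-processing of the hard parcellation.
##
## Components and morphology run over edge adjacency (triangles sharing an
## edge), not vertex adjacency: single-vertex pinches must not bridge
## parcels. Erosion and dilation are synchronous (two-phase) passes so the
## result does not depend on triangle visiting order.

#' Edge-connected components of one sub-parcel
#'
#' @param labels Integer per-triangle label vector (`NA` = unlabeled).
#' @param label The sub-parcel label to analyze.
#' @param surface A [labeled_surface()].
#' @return List of integer triangle vectors, ordered by component size
#'   descending, ties by smallest member triangle index; each component
#'   sorted ascending.
#' @export
connected_components <- function(labels, label, surface) {
  tris <- which(!is.na(labels) & labels == label)
  if (!length(tris)) return(list())
  in_set <- logical(length(labels))
  in_set[tris] <- TRUE
  seen <- logical(length(labels))
  comps <- list()
  for (t0 in tris) {
    if (seen[t0]) next
    queue <- t0
    seen[t0] <- TRUE
    comp <- integer()
    while (length(queue)) {
      t <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, t)
      nb <- surface$edge_adj[[t]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  sizes <- vapply(comps, length, 1L)
  firsts <- vapply(comps, min, 1L)
  comps[order(-sizes, firsts)]
}

#' Remove small connected components with second-label reassignment
#'
#' For every sub-parcel, only the largest edge-connected component is kept.
#' Each triangle of a smaller component takes its second most probable label
#' if that label occurs among its edge-neighbors' current labels; otherwise
#' it becomes unlabeled.
#'
#' @param parc A `hard_parcellation`.
#' @param pmap The `probability_map` the parcellation was hardened from.
#' @param surface A [labeled_surface()].
#' @return The updated `hard_parcellation`, with attribute `"reassigned"` and
#'   `"unlabeled"` counts.
#' @export
remove_small_components <- function(parc, pmap, surface) {
  labels <- parc$labels
  reassigned <- 0L
  removed <- 0L
  for (lab in sort(parc$label_table$label)) {
    comps <- connected_components(labels, lab, surface)
    if (length(comps) <= 1L) next
    for (comp in comps[-1L]) {
      for (t in comp) {
        entry <- pmap[[as.character(t)]]
        second <- if (!is.null(entry) && length(entry$labels) >= 2L)
          entry$labels[2L] else NA_integer_
        nb_labels <- labels[surface$edge_adj[[t]]]
        if (!is.na(second) && second %in% nb_labels[!is.na(nb_labels)]) {
          labels[t] <- second
          reassigned <- reassigned + 1L
        } else {
          labels[t] <- NA_integer_
          removed <- removed + 1L
        }
      }
    }
  }
  out <- refresh_parcellation(parc, labels)
  attr(out, "reassigned") <- reassigned
  attr(out, "unlabeled") <- removed
  out
}

#' Morphological opening of the label field
#'
#' One synchronous erosion pass (a labeled triangle with at least one
#' edge-neighbor carrying a different label or no label becomes unlabeled)
#' followed by one synchronous dilation pass (an unlabeled triangle with at
#' least one labeled edge-neighbor takes the majority label among them, ties
#' to the lowest label). Removes isolated label speckles; never creates a
#' label that was absent before the pass.
#'
#' @param parc A `hard_parcellation`.
#' @param surface A [labeled_surface()].
#' @return The updated `hard_parcellation`.
#' @export
label_opening <- function(parc, surface) {
  labels <- parc$labels
  nt <- length(labels)
  eroded <- labels
  for (t in seq_len(nt)) {
    if (is.na(labels[t])) next
    nb <- surface$edge_adj[[t]]
    if (any(is.na(labels[nb]) | labels[nb] != labels[t]))
      eroded[t] <- NA_integer_
  }
  dilated <- eroded
  for (t in seq_len(nt)) {
    if (!is.na(eroded[t])) next
    nb_lab <- eroded[surface$edge_adj[[t]]]
    nb_lab <- nb_lab[!is.na(nb_lab)]
    if (!length(nb_lab)) next
    tab <- table(nb_lab)
    best <- as.integer(names(tab)[tab == max(tab)])
    dilated[t] <- min(best)
  }
  refresh_parcellation(parc, dilated)
}

#' Full Step-6 post-processing
#'
#' [remove_small_components()] followed by [label_opening()], in the order
#' the method defines.
#'
#' @inheritParams remove_small_components
#' @return The post-processed `hard_parcellation`.
#' @export
postprocess_parcellation <- function(parc, pmap, surface) {
  parc <- remove_small_components(parc, pmap, surface)
  label_opening(parc, surface)
}

# Rebuild triangle counts (and drop emptied rows is left to callers wanting
# it; the table keeps all labels for traceability).
refresh_parcellation <- function(parc, labels) {
  tab <- parc$label_table
  tab$n_triangles <- vapply(tab$label,
                            function(l) sum(labels == l, na.rm = TRUE), 1L)
  structure(list(labels = labels, label_table = tab),
            class = "hard_parcellation")
}
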