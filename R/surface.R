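## Labeled triangle surfaces.
##
## A labeled surface is a triangle mesh with one anatomical region label per
## vertex (as produced by FreeSurfer-style pipelines) plus a per-triangle label
## derived from the vertex labels, and two precomputed adjacency structures:
## vertex adjacency (triangles sharing at least one vertex — the neighborhood
## used for probability-map accumulation) and edge adjacency (triangles sharing
## an edge, at most 3 — the neighborhood used for connected components and
## label morphology). Triangle and vertex indices are 1-based.

#' Construct a labeled surface
#'
#' @param vertices V x 3 numeric matrix of coordinates in mm.
#' @param triangles T x 3 integer matrix of 1-based vertex indices.
#' @param vertex_labels Integer vector of length V: the anatomical region code
#'   of each vertex.
#' @param label_table Optional data frame with columns `label` (integer) and
#'   `name` (region code string). Defaults to names `R<label>`.
#' @return An object of class `labeled_surface` with fields `vertices`,
#'   `triangles`, `vertex_labels`, `triangle_labels`, `vertex_adj`,
#'   `edge_adj`, `label_table`.
#' @export
labeled_surface <- function(vertices, triangles, vertex_labels,
                            label_table = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    cp_stop("vertices and triangles must have 3 columns")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv))
    cp_stop("triangle vertex indices out of range 1..%d", nv)
  vertex_labels <- as.integer(vertex_labels)
  if (length(vertex_labels) != nv)
    cp_stop("label count (%d) does not match vertex count (%d)",
            length(vertex_labels), nv)
  if (is.null(label_table)) {
    lev <- sort(unique(vertex_labels))
    label_table <- data.frame(label = lev, name = paste0("R", lev),
                              stringsAsFactors = FALSE)
  }
  adj <- build_triangle_adjacency(triangles, nv)
  structure(list(
    vertices = vertices, triangles = triangles,
    vertex_labels = vertex_labels,
    triangle_labels = derive_triangle_labels(triangles, vertex_labels),
    vertex_adj = adj$vertex_adj, edge_adj = adj$edge_adj,
    label_table = label_table
  ), class = "labeled_surface")
}

#' @export
print.labeled_surface <- function(x, ...) {
  cat(sprintf("labeled_surface: %d vertices, %d triangles, %d regions\n",
              nrow(x$vertices), nrow(x$triangles), nrow(x$label_table)))
  invisible(x)
}

# Vertex- and edge-adjacency lists over triangles, excluding self.
build_triangle_adjacency <- function(triangles, nv) {
  nt <- nrow(triangles)
  tri_of_vertex <- split(rep(seq_len(nt), 3L), as.vector(triangles))
  vertex_adj <- vector("list", nt)
  for (i in seq_len(nt)) {
    nb <- unique(unlist(tri_of_vertex[as.character(triangles[i, ])],
                        use.names = FALSE))
    vertex_adj[[i]] <- sort(nb[nb != i])
  }
  # edges keyed by sorted vertex pair, encoded as a single double
  v1 <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  v2 <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  lo <- pmin(v1, v2); hi <- pmax(v1, v2)
  key <- as.numeric(lo) * (nv + 1) + hi
  tri_of_edge <- split(rep(seq_len(nt), 3L), key)
  edge_adj <- vector("list", nt)
  for (tris in tri_of_edge) {
    if (length(tris) < 2L) next
    for (t in tris) edge_adj[[t]] <- c(edge_adj[[t]], setdiff(tris, t))
  }
  edge_adj <- lapply(edge_adj, function(x) if (is.null(x)) integer() else sort(unique(x)))
  list(vertex_adj = vertex_adj, edge_adj = edge_adj)
}

#' Derive per-triangle labels from vertex labels
#'
#' Majority label of a triangle's three vertices; when all three differ, the
#' label of the lowest-index vertex wins. The anatomical atlas labels vertices
#' only, so a deterministic triangle rule is needed by the filtering and
#' merging stages.
#'
#' @param triangles T x 3 integer matrix of vertex indices.
#' @param vertex_labels Integer vector of per-vertex region codes.
#' @return Integer vector of length T.
#' @export
derive_triangle_labels <- function(triangles, vertex_labels) {
  l1 <- vertex_labels[triangles[, 1L]]
  l2 <- vertex_labels[triangles[, 2L]]
  l3 <- vertex_labels[triangles[, 3L]]
  out <- l1                               # default covers l1==l2, l1==l3 and all-differ
  out[l2 == l3 & l1 != l2] <- l2[l2 == l3 & l1 != l2]
  all_diff <- l1 != l2 & l2 != l3 & l1 != l3
  if (any(all_diff)) {
    idx <- which(all_diff)
    lowv <- max.col(-triangles[idx, , drop = FALSE], ties.method = "first")
    labs <- cbind(l1, l2, l3)[idx, , drop = FALSE]
    out[idx] <- labs[cbind(seq_along(idx), lowv)]
  }
  as.integer(out)
}

#' Map between region codes and integer labels
#'
#' @param surface A [labeled_surface()].
#' @param label Integer label(s).
#' @param name Region code string(s).
#' @return `region_name()` returns code strings; `region_label()` returns
#'   integer labels (erroring on unknown codes).
#' @export
region_name <- function(surface, label) {
  lt <- surface$label_table
  lt$name[match(label, lt$label)]
}

#' @rdname region_name
#' @export
region_label <- function(surface, name) {
  lt <- surface$label_table
  out <- lt$label[match(name, lt$name)]
  if (anyNA(out))
    cp_stop("unknown region code(s): %s",
            paste(unique(name[is.na(out)]), collapse = ", "))
  out
}
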