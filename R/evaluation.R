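## Reproducibility and similarity evaluation.
##
## Connectivity matrices are binary, symmetric, parcel-by-parcel incidence
## matrices built from whole tractograms. Matrix Dice uses the nonzero cells
## of the upper triangle (diagonal included: intra-parcel connections are not
## excluded) as the set, so symmetry is not double-counted; this convention
## is recorded in the matrix attributes.

#' Build a binary parcel connectivity matrix for one subject
#'
#' Every fiber of the whole tractogram is intersected with the mesh; when
#' both end triangles carry final sub-parcel labels `a` and `b`, cells
#' `[a, b]` and `[b, a]` are set to 1. Fibers with unresolved or unlabeled
#' ends are ignored.
#'
#' @param t The subject's [tractogram()].
#' @param parc A `hard_parcellation`.
#' @param surface A [labeled_surface()].
#' @param cfg A [pipeline_config()].
#' @param grid Optional [build_triangle_grid()] index.
#' @return An n x n binary symmetric matrix (n = number of sub-parcels),
#'   dimnames = sub-parcel labels, with attribute `"set_convention"`.
#' @export
build_connectivity_matrix <- function(t, parc, surface, cfg, grid = NULL) {
  if (length(parc$labels) != nrow(surface$triangles))
    cp_stop("parcellation and surface triangle counts differ")
  ends <- locate_tractogram_endpoints(t, surface, cfg, grid)
  labs <- sort(parc$label_table$label)
  n <- length(labs)
  M <- matrix(0L, n, n, dimnames = list(labs, labs))
  a <- parc$labels[ends$tri_start]
  b <- parc$labels[ends$tri_end]
  ok <- !is.na(ends$tri_start) & !is.na(ends$tri_end) & !is.na(a) & !is.na(b)
  if (any(ok)) {
    ia <- match(a[ok], labs)
    ib <- match(b[ok], labs)
    M[cbind(ia, ib)] <- 1L
    M[cbind(ib, ia)] <- 1L
  }
  attr(M, "set_convention") <- "upper-triangle incl. diagonal, nonzero cells"
  M
}

#' Dice coefficient of two sets
#'
#' `2|A n B| / (|A| + |B|)`. Both-empty input is defined as 0 with a warning.
#'
#' @param A,B Vectors interpreted as sets (duplicates removed).
#' @return A fraction in \[0, 1\].
#' @export
dice_sets <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) && !length(B)) {
    warning("dice_sets: both sets empty, returning 0")
    return(0)
  }
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

#' Mean pairwise Dice between per-subject connectivity matrices
#'
#' The set for each subject is the index list of nonzero upper-triangle
#' (diagonal included) cells of its matrix; Dice is computed for every
#' unordered subject pair and averaged.
#'
#' @param matrices List of equally-shaped binary matrices with identical
#'   dimnames ([build_connectivity_matrix()]).
#' @return List with `mean` and `pairs` (data frame `i`, `j`, `dice`).
#' @export
pairwise_matrix_dice <- function(matrices) {
  if (length(matrices) < 2L) cp_stop("need at least two subjects")
  dims <- vapply(matrices, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    cp_stop("connectivity matrices have mismatched shapes: %s",
            paste(unique(dims), collapse = " vs "))
  upper_cells <- function(M) which(M != 0 & upper.tri(M, diag = TRUE))
  sets <- lapply(matrices, upper_cells)
  pairs <- utils::combn(length(matrices), 2L)
  d <- apply(pairs, 2L, function(pr) dice_sets(sets[[pr[1L]]], sets[[pr[2L]]]))
  list(mean = mean(d),
       pairs = data.frame(i = pairs[1L, ], j = pairs[2L, ], dice = d))
}

#' Compare two parcellations parcel-by-parcel
#'
#' Dice over triangle sets for every parcel pair; for each parcel of A its
#' best match in B (ties to the lowest B label); the atlas-pair score is the
#' symmetrized mean of the best-match Dice in both directions. Best-match
#' values of the A-to-B direction are binned over
#' \[0.5,0.6), \[0.6,0.7), \[0.7,0.8), \[0.8,0.9).
#'
#' @param parcA,parcB `hard_parcellation`s on the same mesh topology.
#' @return List with `dice` (matrix, A parcels x B parcels), `best_matches`
#'   (data frame), `score`, `bins` (named counts).
#' @export
compare_parcellations <- function(parcA, parcB) {
  if (length(parcA$labels) != length(parcB$labels))
    cp_stop("parcellations are on different mesh topologies")
  sets_of <- function(p) {
    labs <- sort(p$label_table$label)
    labs <- labs[vapply(labs, function(l) any(!is.na(p$labels) & p$labels == l),
                        TRUE)]
    stats::setNames(lapply(labs, function(l) which(!is.na(p$labels) &
                                                     p$labels == l)),
                    labs)
  }
  SA <- sets_of(parcA)
  SB <- sets_of(parcB)
  D <- matrix(0, length(SA), length(SB),
              dimnames = list(names(SA), names(SB)))
  for (i in seq_along(SA))
    for (j in seq_along(SB))
      D[i, j] <- dice_sets(SA[[i]], SB[[j]])
  best_of <- function(D) {
    j <- max.col(D, ties.method = "first")
    data.frame(parcel = rownames(D), match = colnames(D)[j],
               dice = D[cbind(seq_len(nrow(D)), j)],
               stringsAsFactors = FALSE)
  }
  ab <- best_of(D)
  ba <- best_of(t(D))
  breaks <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  bins <- stats::setNames(integer(4L), sprintf("[%.1f,%.1f)", breaks[-5L],
                                               breaks[-1L]))
  for (k in 1:4)
    bins[k] <- sum(ab$dice >= breaks[k] & ab$dice < breaks[k + 1L])
  list(dice = D, best_matches = ab,
       score = (mean(ab$dice) + mean(ba$dice)) / 2, bins = bins)
}

#' Coefficient of variation
#'
#' Population standard deviation divided by the mean.
#'
#' @param values Numeric vector with positive mean.
#' @return `sigma / mu`.
#' @export
coefficient_of_variation <- function(values) {
  mu <- mean(values)
  if (!is.finite(mu) || mu <= 0) cp_stop("coefficient_of_variation: mean must be > 0")
  sqrt(mean((values - mu)^2)) / mu
}

#' Map a volumetric label image onto mesh vertices
#'
#' Each vertex takes the label of the nearest labeled (nonzero) voxel center;
#' ties break to the lowest voxel linear index (column-major, 1-based).
#'
#' @param volume A `label_volume` (see [label_volume()] /
#'   [read_nifti_labels()]) or a path to a NIfTI file.
#' @param surface A [labeled_surface()] in the same space.
#' @return Integer vector of per-vertex labels.
#' @export
map_volume_labels_to_mesh <- function(volume, surface) {
  if (is.character(volume)) volume <- read_nifti_labels(volume)
  stopifnot(inherits(volume, "label_volume"))
  lin <- which(volume$data != 0)
  if (!length(lin)) cp_stop("volume has no labeled voxels")
  dm <- dim(volume$data)
  ijk <- cbind((lin - 1L) %% dm[1L],
               ((lin - 1L) %/% dm[1L]) %% dm[2L],
               (lin - 1L) %/% (dm[1L] * dm[2L]))
  centers <- cbind(ijk, 1) %*% t(volume$affine)
  centers <- centers[, 1:3, drop = FALSE]
  labs <- as.integer(volume$data[lin])
  V <- surface$vertices
  out <- integer(nrow(V))
  c2 <- rowSums(centers^2)
  for (i in seq_len(nrow(V))) {
    d2 <- c2 - 2 * drop(centers %*% V[i, ]) + sum(V[i, ]^2)
    w <- order(d2, lin)[1L]          # tie -> lowest linear index
    out[i] <- labs[w]
  }
  out
}
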