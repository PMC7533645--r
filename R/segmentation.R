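## Step 1 — fiber-bundle segmentation.
##
## Each tractogram fiber is compared against every atlas fiber with the
## maximum corresponding-point Euclidean distance, evaluated in both
## orientations (whole-brain tractograms store about half of the fibers
## reversed). A fiber is claimed by the bundle holding the closest atlas fiber
## among the bundles whose per-bundle threshold it satisfies; fibers failing
## every threshold stay unlabeled.

#' Corresponding-point distance between two 21-point fibers
#'
#' `d_direct = max_k ||a_k - b_k||`, `d_flip = max_k ||a_k - b_(22-k)||`; the
#' smaller of the two wins, ties favoring the direct orientation.
#'
#' @param a,b 21 x 3 matrices.
#' @return List with `distance_mm` and logical `flipped`.
#' @export
fiber_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L)
    cp_stop("fiber_distance: point-count mismatch (%d vs %d)", nrow(a), nrow(b))
  d_direct <- sqrt(max(rowSums((a - b)^2)))
  d_flip <- sqrt(max(rowSums((a - reverse_streamline(b))^2)))
  if (d_flip < d_direct) list(distance_mm = d_flip, flipped = TRUE)
  else list(distance_mm = d_direct, flipped = FALSE)
}

# Flatten a list of k-point fibers into an n x (3k) matrix, points
# concatenated as (p1x p1y p1z p2x ...).
flatten_fibers <- function(fibers) {
  t(vapply(fibers, function(f) as.numeric(t(f)),
           numeric(3L * nrow(fibers[[1L]]))))
}

# Squared corresponding-point max distance between all rows of Fa and Fb
# (both n x 3k flattened): returns n_a x n_b matrix.
cross_max_sqdist <- function(Fa, Fb, k = 21L) {
  # direct per-coordinate differences (not the |x|^2+|y|^2-2xy expansion,
  # whose cancellation error breaks exact-match distances)
  best <- NULL
  for (p in seq_len(k)) {
    cols <- (3L * (p - 1L) + 1L):(3L * p)
    d2 <- outer(Fa[, cols[1L]], Fb[, cols[1L]], `-`)^2 +
      outer(Fa[, cols[2L]], Fb[, cols[2L]], `-`)^2 +
      outer(Fa[, cols[3L]], Fb[, cols[3L]], `-`)^2
    best <- if (is.null(best)) d2 else pmax(best, d2)
  }
  best
}

#' Segment a tractogram against a bundle atlas
#'
#' @param t A [tractogram()] whose fibers are resampled to 21 points and
#'   co-registered with the atlas.
#' @param atlas A [bundle_atlas()].
#' @return Data frame with one row per labeled fiber: `fiber_id` (0-based
#'   tractogram index), `bundle`, `distance_mm`, `flipped`. Fibers failing
#'   every bundle threshold are omitted. Ties between bundles at identical
#'   distance are broken by bundle name ascending.
#' @export
segment_tractogram <- function(t, atlas) {
  stopifnot(inherits(t, "tractogram"), inherits(atlas, "bundle_atlas"))
  if (!length(atlas$bundles)) cp_stop("empty atlas")
  npts <- vapply(t$streamlines, nrow, 1L)
  if (length(npts) && any(npts != 21L))
    cp_stop("tractogram must be resampled to 21 points before segmentation")
  empty <- data.frame(fiber_id = integer(), bundle = character(),
                      distance_mm = numeric(), flipped = logical(),
                      stringsAsFactors = FALSE)
  if (!length(t$streamlines)) return(empty)

  bundle_names <- names(atlas$bundles)             # sorted ascending
  atlas_fibers <- unlist(lapply(atlas$bundles, function(b) b$fibers),
                         recursive = FALSE)
  fiber_bundle <- rep(seq_along(atlas$bundles),
                      vapply(atlas$bundles, function(b) length(b$fibers), 1L))
  thresholds <- vapply(atlas$bundles, function(b) b$threshold_mm, 1)

  Fs <- flatten_fibers(t$streamlines)
  Fa <- flatten_fibers(atlas_fibers)
  Fa_rev <- flatten_fibers(lapply(atlas_fibers, reverse_streamline))
  D2d <- cross_max_sqdist(Fs, Fa)
  D2f <- cross_max_sqdist(Fs, Fa_rev)
  flip_won <- D2f < D2d                            # ties favor direct
  D <- sqrt(pmin(D2d, D2f))

  # per-bundle minimum distance and arg-min atlas fiber, per subject fiber
  n <- nrow(D)
  nb <- length(bundle_names)
  dmin <- matrix(Inf, n, nb)
  amin <- matrix(1L, n, nb)
  for (b in seq_len(nb)) {
    cols <- which(fiber_bundle == b)
    Db <- D[, cols, drop = FALSE]
    w <- max.col(-Db, ties.method = "first")
    dmin[, b] <- Db[cbind(seq_len(n), w)]
    amin[, b] <- cols[w]
  }
  masked <- dmin
  masked[!(dmin <= rep(thresholds, each = n))] <- Inf
  win <- max.col(-masked, ties.method = "first")   # first index = name asc
  win_d <- masked[cbind(seq_len(n), win)]
  keep <- is.finite(win_d)
  if (!any(keep)) return(empty)
  res <- data.frame(
    fiber_id = which(keep) - 1L,
    bundle = bundle_names[win[keep]],
    distance_mm = win_d[keep],
    flipped = flip_won[cbind(which(keep), amin[cbind(which(keep), win[keep])])],
    stringsAsFactors = FALSE)
  `rownames<-`(res, NULL)
}
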