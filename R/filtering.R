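## Step 4 — fiber filtering and alignment.
##
## A fiber survives iff the unordered pair of anatomical labels of its two
## end triangles equals the unordered region pair of its bundle (for
## intra-region bundles, both ends must lie in that single region). Survivors
## are then oriented along the bundle's atlas centroid: if the reversed fiber
## is closer to the centroid under the max corresponding-point distance, the
## point order and the (tri_start, tri_end) pair are swapped.

#' Remove fibers whose end-triangle labels contradict the bundle definition
#'
#' @param bundle A [bundle()].
#' @param records Data frame from [intersect_tractogram()] restricted to this
#'   bundle (`fiber_id`, `tri_start`, `tri_end`).
#' @param surface A [labeled_surface()].
#' @return The surviving rows of `records`; the removed count is attached as
#'   attribute `"removed"`.
#' @export
filter_misclassified <- function(bundle, records, surface) {
  want <- sort(region_label(surface, c(bundle$region_start, bundle$region_end)))
  ls <- surface$triangle_labels[records$tri_start]
  le <- surface$triangle_labels[records$tri_end]
  keep <- pmin(ls, le) == want[1L] & pmax(ls, le) == want[2L]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Align fibers of one bundle to the atlas centroid
#'
#' @param t The subject's [tractogram()] (21-point fibers).
#' @param records Filtered records for one bundle (`fiber_id`, `tri_start`,
#'   `tri_end`).
#' @param bundle The [bundle()] whose centroid defines the reference
#'   orientation.
#' @return List with `records` (end triangles swapped where the fiber was
#'   reversed, plus a logical `flipped` column) and `fibers` (the oriented
#'   21 x 3 matrices, in record order).
#' @export
align_fibers <- function(t, records, bundle) {
  n <- nrow(records)
  fibers <- vector("list", n)
  flipped <- logical(n)
  cen <- bundle$centroid
  cen_rev <- reverse_streamline(cen)
  for (k in seq_len(n)) {
    f <- t$streamlines[[records$fiber_id[k] + 1L]]
    d_direct <- max(rowSums((f - cen)^2))
    d_flip <- max(rowSums((f - cen_rev)^2))
    if (d_flip < d_direct) {
      fibers[[k]] <- reverse_streamline(f)
      flipped[k] <- TRUE
    } else {
      fibers[[k]] <- f
    }
  }
  recs <- records
  if (any(flipped)) {
    tmp <- recs$tri_start[flipped]
    recs$tri_start[flipped] <- recs$tri_end[flipped]
    recs$tri_end[flipped] <- tmp
  }
  recs$flipped <- flipped
  list(records = recs, fibers = fibers)
}

#' Filter and align a whole subject against the atlas
#'
#' Convenience wrapper running [filter_misclassified()] then [align_fibers()]
#' for every bundle present in `records`.
#'
#' @param t The subject's [tractogram()].
#' @param records Data frame from [intersect_tractogram()] (`fiber_id`,
#'   `bundle`, `tri_start`, `tri_end`).
#' @param atlas A [bundle_atlas()].
#' @param surface A [labeled_surface()].
#' @return Data frame of surviving, aligned records (`fiber_id`, `bundle`,
#'   `tri_start`, `tri_end`, `flipped`), with attribute `"removed"` giving the
#'   number filtered out.
#' @export
filter_tractogram <- function(t, records, atlas, surface) {
  removed <- 0L
  parts <- lapply(sort(unique(records$bundle)), function(bn) {
    b <- atlas$bundles[[bn]]
    if (is.null(b)) cp_stop("records reference unknown bundle '%s'", bn)
    recs <- records[records$bundle == bn, , drop = FALSE]
    filt <- filter_misclassified(b, recs, surface)
    removed <<- removed + attr(filt, "removed")
    if (!nrow(filt)) return(NULL)
    align_fibers(t, filt, b)$records
  })
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(fiber_id = integer(), bundle = character(),
                      tri_start = integer(), tri_end = integer(),
                      flipped = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
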