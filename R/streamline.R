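## Streamlines and tractograms.
##
## A streamline ("fiber") is an n x 3 numeric matrix of ordered 3-D points in
## mm. A tractogram is a list of streamlines plus a free-text coordinate-space
## tag; streamline ids are implicit 0-based positions (id i = element i + 1),
## matching the on-disk record order of TCK/TRK files.

#' Construct a tractogram
#'
#' @param streamlines List of n x 3 numeric matrices (n >= 2 points each, all
#'   coordinates finite).
#' @param space Free-text coordinate-space tag (e.g. `"subject-T1"`, `"MNI"`).
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, space = "unknown") {
  if (!is.list(streamlines)) cp_stop("streamlines must be a list of matrices")
  streamlines <- lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    if (is.data.frame(s)) s <- as.matrix(s)
    if (!is.matrix(s) || ncol(s) != 3L)
      cp_stop("streamline %d is not an n x 3 matrix", i)
    storage.mode(s) <- "double"
    if (nrow(s) < 2L)
      cp_stop("streamline %d has fewer than 2 points", i)
    if (!all(is.finite(s)))
      cp_stop("streamline %d contains non-finite coordinates", i)
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, space = as.character(space)),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 1L)
  cat(sprintf("tractogram: %d streamlines (%s points each), space '%s'\n",
              length(np),
              if (length(np) && min(np) == max(np)) min(np)
              else sprintf("%d-%d", min(np), max(np)),
              x$space))
  invisible(x)
}

#' Resample a streamline to n equidistant points
#'
#' Points are placed at equal arc-length intervals along the input polyline;
#' the first and last points are preserved exactly.
#'
#' @param s An m x 3 numeric matrix (m >= 2).
#' @param n Output point count (>= 2). Bundle atlases conventionally use 21.
#' @return An n x 3 matrix.
#' @export
resample_streamline <- function(s, n = 21L) {
  s <- as.matrix(s)
  n <- as.integer(n)
  if (n < 2L) cp_stop("n must be >= 2")
  if (nrow(s) < 2L) cp_stop("streamline must have >= 2 points")
  seg <- sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) cp_stop("degenerate zero-length streamline")
  cum <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n)
  # piecewise-linear interpolation along cumulative arc length, per coordinate
  out <- vapply(1:3, function(j) stats::approx(cum, s[, j], xout = target,
                                               ties = "ordered")$y,
                numeric(n))
  out <- matrix(out, nrow = n)
  out[1L, ] <- s[1L, ]
  out[n, ] <- s[nrow(s), ]
  out
}

#' Resample every streamline of a tractogram
#'
#' @param t A [tractogram()].
#' @inheritParams resample_streamline
#' @return A `tractogram` whose streamlines all have `n` points.
#' @export
resample_tractogram <- function(t, n = 21L) {
  stopifnot(inherits(t, "tractogram"))
  t$streamlines <- lapply(t$streamlines, resample_streamline, n = n)
  t
}

# Arc length of a polyline (internal).
polyline_length <- function(s) {
  sum(sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
}

# Reverse point order of a streamline (internal).
reverse_streamline <- function(s) s[rev(seq_len(nrow(s))), , drop = FALSE]
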