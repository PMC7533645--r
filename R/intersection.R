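## Step 3 — streamline-mesh intersection.
##
## Each fiber extremity is resolved to a mesh triangle in two phases:
## (1) a Moller-Trumbore ray cast from the penultimate point through the
## endpoint, accepted if the hit lies no more than ray_epsilon_mm beyond the
## endpoint; (2) if no ray hit, the nearest triangle by point-to-triangle
## distance. Both phases only consider triangles whose axis-aligned bounding
## box lies within search_radius_mm of the endpoint, found through a uniform
## grid over triangle AABBs (exact: the grid query covers the whole search
## box). Tolerances: determinant cutoff 1e-12, barycentric slack 1e-9.

MT_DET_EPS <- 1e-12
MT_BARY_EPS <- 1e-9

#' Moller-Trumbore ray/triangle intersection
#'
#' @param origin Numeric length-3 ray origin.
#' @param direction Numeric length-3 ray direction (non-zero; normalized
#'   internally so the ray parameter `t` is in mm).
#' @param tri 3 x 3 matrix, one triangle vertex per row.
#' @return List with `hit` (logical), and when applicable `t` (signed ray
#'   parameter, mm), `u`, `v` (barycentric coordinates of the hit).
#' @export
moller_trumbore <- function(origin, direction, tri) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) cp_stop("zero ray direction")
  d <- direction / nrm
  tri <- as.matrix(tri)
  e1 <- tri[2L, ] - tri[1L, ]
  e2 <- tri[3L, ] - tri[1L, ]
  p <- cross3(d, e2)
  det <- sum(e1 * p)
  if (abs(det) <= MT_DET_EPS) return(list(hit = FALSE))
  inv <- 1 / det
  tvec <- origin - tri[1L, ]
  u <- sum(tvec * p) * inv
  q <- cross3(tvec, e1)
  v <- sum(d * q) * inv
  tt <- sum(e2 * q) * inv
  hit <- u >= -MT_BARY_EPS && v >= -MT_BARY_EPS &&
    u + v <= 1 + MT_BARY_EPS && tt >= -MT_BARY_EPS
  if (!hit) return(list(hit = FALSE))
  list(hit = TRUE, t = tt, u = u, v = v)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Vectorized Moller-Trumbore: one ray against many triangles.
# V0, V1, V2 are n x 3 matrices; direction must already be unit length.
mt_batch <- function(origin, d, V0, V1, V2) {
  E1 <- V1 - V0
  E2 <- V2 - V0
  P <- cbind(d[2L] * E2[, 3L] - d[3L] * E2[, 2L],
             d[3L] * E2[, 1L] - d[1L] * E2[, 3L],
             d[1L] * E2[, 2L] - d[2L] * E2[, 1L])
  det <- rowSums(E1 * P)
  Tv <- matrix(origin, nrow(V0), 3L, byrow = TRUE) - V0
  Q <- cbind(Tv[, 2L] * E1[, 3L] - Tv[, 3L] * E1[, 2L],
             Tv[, 3L] * E1[, 1L] - Tv[, 1L] * E1[, 3L],
             Tv[, 1L] * E1[, 2L] - Tv[, 2L] * E1[, 1L])
  inv <- ifelse(abs(det) <= MT_DET_EPS, NA_real_, 1 / det)
  u <- rowSums(Tv * P) * inv
  v <- (Q[, 1L] * d[1L] + Q[, 2L] * d[2L] + Q[, 3L] * d[3L]) * inv
  tt <- rowSums(E2 * Q) * inv
  hit <- !is.na(inv) & u >= -MT_BARY_EPS & v >= -MT_BARY_EPS &
    u + v <= 1 + MT_BARY_EPS & tt >= -MT_BARY_EPS
  list(hit = hit, t = tt, u = u, v = v)
}

## ---- uniform grid over triangle AABBs ------------------------------------

#' Build a uniform-grid spatial index over a surface's triangles
#'
#' @param surface A [labeled_surface()].
#' @param cell_mm Grid cell edge length; defaults to the mean triangle edge
#'   length (clamped to be at least 1 mm).
#' @return Opaque index object consumed by [locate_endpoint()].
#' @export
build_triangle_grid <- function(surface, cell_mm = NULL) {
  V <- surface$vertices
  Tm <- surface$triangles
  A <- V[Tm[, 1L], , drop = FALSE]
  B <- V[Tm[, 2L], , drop = FALSE]
  C <- V[Tm[, 3L], , drop = FALSE]
  if (is.null(cell_mm)) {
    el <- sqrt(rowSums((A - B)^2))
    cell_mm <- max(1, mean(el))
  }
  lo <- pmin(A, B, C)
  hi <- pmax(A, B, C)
  origin <- apply(lo, 2L, min)
  idx_lo <- floor(sweep(lo, 2L, origin) / cell_mm)
  idx_hi <- floor(sweep(hi, 2L, origin) / cell_mm)
  cells <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(Tm))) {
    for (ix in idx_lo[i, 1L]:idx_hi[i, 1L])
      for (iy in idx_lo[i, 2L]:idx_hi[i, 2L])
        for (iz in idx_lo[i, 3L]:idx_hi[i, 3L]) {
          k <- paste(ix, iy, iz, sep = "_")
          cells[[k]] <- c(cells[[k]], i)
        }
  }
  list(cells = cells, origin = origin, cell_mm = cell_mm,
       aabb_lo = lo, aabb_hi = hi, V0 = A, V1 = B, V2 = C)
}

# Triangles whose AABB lies within radius r of point p.
grid_query <- function(grid, p, r) {
  lo <- floor((p - r - grid$origin) / grid$cell_mm)
  hi <- floor((p + r - grid$origin) / grid$cell_mm)
  out <- integer()
  for (ix in lo[1L]:hi[1L])
    for (iy in lo[2L]:hi[2L])
      for (iz in lo[3L]:hi[3L]) {
        v <- grid$cells[[paste(ix, iy, iz, sep = "_")]]
        if (!is.null(v)) out <- c(out, v)
      }
  out <- unique(out)
  if (!length(out)) return(out)
  # exact AABB-to-point distance filter
  dlo <- grid$aabb_lo[out, , drop = FALSE] - matrix(p, length(out), 3L, byrow = TRUE)
  dhi <- matrix(p, length(out), 3L, byrow = TRUE) - grid$aabb_hi[out, , drop = FALSE]
  gap <- pmax(dlo, dhi, 0)
  sort(out[rowSums(gap^2) <= r^2])
}

# Squared distance from point p to each triangle (rows of V0/V1/V2).
# Closest-point-on-triangle (Ericson, Real-Time Collision Detection).
point_triangle_sqdist <- function(p, V0, V1, V2) {
  n <- nrow(V0)
  P <- matrix(p, n, 3L, byrow = TRUE)
  ab <- V1 - V0; ac <- V2 - V0; ap <- P - V0
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - V1
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - V2
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  # interior barycentric solution
  v <- vb / denom
  w <- vc / denom
  Q <- V0 + ab * v + ac * w
  # region tests override the interior solution where applicable
  reg1 <- d1 <= 0 & d2 <= 0                                   # vertex A
  Q[reg1, ] <- V0[reg1, ]
  reg2 <- !reg1 & d3 >= 0 & d4 <= d3                          # vertex B
  Q[reg2, ] <- V1[reg2, ]
  reg3 <- !reg1 & !reg2 & d6 >= 0 & d5 <= d6                  # vertex C
  Q[reg3, ] <- V2[reg3, ]
  done <- reg1 | reg2 | reg3
  regAB <- !done & vc <= 0 & d1 >= 0 & d3 <= 0                # edge AB
  if (any(regAB)) {
    tt <- d1[regAB] / (d1[regAB] - d3[regAB])
    Q[regAB, ] <- V0[regAB, , drop = FALSE] + ab[regAB, , drop = FALSE] * tt
  }
  done <- done | regAB
  regAC <- !done & vb <= 0 & d2 >= 0 & d6 <= 0                # edge AC
  if (any(regAC)) {
    tt <- d2[regAC] / (d2[regAC] - d6[regAC])
    Q[regAC, ] <- V0[regAC, , drop = FALSE] + ac[regAC, , drop = FALSE] * tt
  }
  done <- done | regAC
  regBC <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(regBC)) {
    tt <- (d4[regBC] - d3[regBC]) /
      ((d4[regBC] - d3[regBC]) + (d5[regBC] - d6[regBC]))
    Q[regBC, ] <- V1[regBC, , drop = FALSE] +
      (V2[regBC, , drop = FALSE] - V1[regBC, , drop = FALSE]) * tt
  }
  rowSums((P - Q)^2)
}

#' Resolve a fiber extremity to a mesh triangle
#'
#' @param fiber An n x 3 matrix (n >= 2).
#' @param end `"first"` or `"last"`.
#' @param surface A [labeled_surface()].
#' @param cfg A [pipeline_config()] (ray extension and search radius).
#' @param grid Optional precomputed [build_triangle_grid()] index.
#' @return A 1-based triangle index, or `NA_integer_` when no triangle lies
#'   within the search radius. Ties break to the lowest triangle index.
#' @export
locate_endpoint <- function(fiber, end = c("last", "first"), surface, cfg,
                            grid = NULL) {
  end <- match.arg(end)
  fiber <- as.matrix(fiber)
  if (nrow(fiber) < 2L) cp_stop("fiber must have >= 2 points")
  if (is.null(grid)) grid <- build_triangle_grid(surface)
  if (end == "first") fiber <- reverse_streamline(fiber)
  p <- fiber[nrow(fiber), ]
  q <- fiber[nrow(fiber) - 1L, ]
  r <- cfg$search_radius_mm
  cand <- grid_query(grid, p, r)
  if (!length(cand)) return(NA_integer_)
  V0 <- grid$V0[cand, , drop = FALSE]
  V1 <- grid$V1[cand, , drop = FALSE]
  V2 <- grid$V2[cand, , drop = FALSE]
  L <- sqrt(sum((p - q)^2))
  if (L > 0) {
    d <- (p - q) / L
    mt <- mt_batch(q, d, V0, V1, V2)
    ok <- mt$hit & mt$t <= L + cfg$ray_epsilon_mm
    if (any(ok)) {
      hp <- matrix(q, sum(ok), 3L, byrow = TRUE) +
        outer(mt$t[ok], d)
      dist_end <- rowSums((hp - matrix(p, sum(ok), 3L, byrow = TRUE))^2)
      w <- which(ok)[order(dist_end, cand[ok])[1L]]
      return(cand[w])
    }
  }
  d2 <- point_triangle_sqdist(p, V0, V1, V2)
  w <- order(d2, cand)[1L]
  if (d2[w] <= r^2) cand[w] else NA_integer_
}

#' Locate both extremities of every fiber in a tractogram
#'
#' @param t A [tractogram()].
#' @inheritParams locate_endpoint
#' @return Data frame with `fiber_id` (0-based), `tri_start`, `tri_end`
#'   (`NA` where unresolved).
#' @export
locate_tractogram_endpoints <- function(t, surface, cfg, grid = NULL) {
  stopifnot(inherits(t, "tractogram"))
  if (!nrow(surface$triangles)) cp_stop("empty surface")
  if (is.null(grid)) grid <- build_triangle_grid(surface)
  n <- length(t$streamlines)
  tri_start <- tri_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- t$streamlines[[i]]
    tri_start[i] <- locate_endpoint(f, "first", surface, cfg, grid)
    tri_end[i] <- locate_endpoint(f, "last", surface, cfg, grid)
  }
  data.frame(fiber_id = seq_len(n) - 1L, tri_start = tri_start,
             tri_end = tri_end)
}

#' Intersect segmented fibers with the cortical mesh
#'
#' @param t The subject's [tractogram()].
#' @param segmented Data frame from [segment_tractogram()] (`fiber_id`,
#'   `bundle`); only these fibers are intersected.
#' @inheritParams locate_endpoint
#' @return Data frame with `fiber_id`, `bundle`, `tri_start`, `tri_end`, one
#'   row per fiber with both ends resolved. The number of dropped fibers is
#'   attached as attribute `"dropped"` and reported via `message()`.
#' @export
intersect_tractogram <- function(t, segmented, surface, cfg, grid = NULL) {
  stopifnot(inherits(t, "tractogram"))
  if (!nrow(surface$triangles)) cp_stop("empty surface")
  if (is.null(grid)) grid <- build_triangle_grid(surface)
  tri_start <- tri_end <- rep(NA_integer_, nrow(segmented))
  for (k in seq_len(nrow(segmented))) {
    f <- t$streamlines[[segmented$fiber_id[k] + 1L]]
    tri_start[k] <- locate_endpoint(f, "first", surface, cfg, grid)
    tri_end[k] <- locate_endpoint(f, "last", surface, cfg, grid)
  }
  keep <- !is.na(tri_start) & !is.na(tri_end)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(sprintf("intersect_tractogram: dropped %d fiber(s) with unresolved ends",
                    dropped))
  out <- data.frame(fiber_id = segmented$fiber_id[keep],
                    bundle = segmented$bundle[keep],
                    tri_start = tri_start[keep], tri_end = tri_end[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}
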