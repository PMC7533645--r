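# Shared fixtures, built lazily and cached for the whole test run.
# Small fixtures (subdivision-2/3 spheres, 3-subject cohorts) back the module
# tests; the default-world cohort and its pipeline run are built once and
# reused by the acceptance criteria.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# icosahedron with uniform labels
tiny_icosahedron <- function(label = 7L) {
  mesh <- make_icosphere(0L, radius = 1)
  labeled_surface(mesh$vertices, mesh$triangles,
                  rep(label, nrow(mesh$vertices)))
}

test_sphere <- function() {
  cached("sphere", make_labeled_sphere(subdivisions = 2L, n_regions = 4L,
                                       seed = 5L, radius = 100,
                                       min_region_triangles = 20L))
}

small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(n_subjects = 3L, subdivisions = 3L, n_regions = 4L,
                         footprints_per_region = 2L, fibers_per_bundle = 16L,
                         sigma = 0.5, seed = 11L))
}

small_run <- function() {
  cached("small_run", run_pipeline(small_cohort(), pipeline_config(),
                                   evaluate = FALSE))
}

# The stated default test world (8 regions, 2-4 footprints per region,
# 10 subjects, sigma = 0.5 mm, 50% flips, 20% distractors).
default_cohort <- function() {
  cached("default_cohort", simulate_cohort(seed = 1L))
}

default_run <- function() {
  cached("default_run", run_pipeline(default_cohort(), pipeline_config(),
                                     evaluate = FALSE))
}

# Independent brute-force oracle for segmentation: plain per-pair loops,
# no flattening or shared code with segment_tractogram's vectorized path.
oracle_segment <- function(t, atlas) {
  bnames <- sort(vapply(atlas$bundles, function(b) b$name, ""))
  rows <- list()
  for (i in seq_along(t$streamlines)) {
    f <- t$streamlines[[i]]
    fr <- f[21:1, , drop = FALSE]
    best_d <- rep(Inf, length(bnames))
    best_fl <- rep(FALSE, length(bnames))
    for (bi in seq_along(bnames)) {
      b <- atlas$bundles[[bnames[bi]]]
      for (af in b$fibers) {
        dd <- sqrt(max(rowSums((f - af)^2)))
        df <- sqrt(max(rowSums((fr - af)^2)))
        d <- min(dd, df)
        if (d < best_d[bi]) {
          best_d[bi] <- d
          best_fl[bi] <- df < dd
        }
      }
    }
    ok <- which(best_d <= vapply(atlas$bundles[bnames],
                                 function(b) b$threshold_mm, 1))
    if (!length(ok)) next
    w <- ok[which.min(best_d[ok])]
    rows[[length(rows) + 1L]] <- data.frame(
      fiber_id = i - 1L, bundle = bnames[w], distance_mm = best_d[w],
      flipped = best_fl[w], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(fiber_id = integer(), bundle = character(),
                      distance_mm = numeric(), flipped = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Closed-form plane + barycentric-sign oracle for ray/triangle intersection.
oracle_ray_triangle <- function(origin, direction, tri) {
  d <- direction / sqrt(sum(direction^2))
  e1 <- tri[2L, ] - tri[1L, ]
  e2 <- tri[3L, ] - tri[1L, ]
  n <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
         e1[3L] * e2[1L] - e1[1L] * e2[3L],
         e1[1L] * e2[2L] - e1[2L] * e2[1L])
  denom <- sum(n * d)
  if (abs(denom) <= 1e-12 * sqrt(sum(n^2)) || abs(denom) == 0)
    return(list(hit = FALSE))
  t <- sum(n * (tri[1L, ] - origin)) / denom
  p <- origin + t * d
  # solve barycentric coordinates from the 2x2 Gram system
  w <- p - tri[1L, ]
  g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
  b1 <- sum(w * e1); b2 <- sum(w * e2)
  det <- g11 * g22 - g12 * g12
  u <- (g22 * b1 - g12 * b2) / det
  v <- (g11 * b2 - g12 * b1) / det
  if (u >= -1e-9 && v >= -1e-9 && u + v <= 1 + 1e-9 && t >= -1e-9)
    list(hit = TRUE, t = t, u = u, v = v, point = p)
  else list(hit = FALSE)
}

# Exhaustive all-triangle endpoint-location oracle (no spatial index), same
# two-phase rules as locate_endpoint.
oracle_locate <- function(fiber, end, surface, cfg) {
  f <- if (end == "first") fiber[rev(seq_len(nrow(fiber))), ] else fiber
  p <- f[nrow(f), ]
  q <- f[nrow(f) - 1L, ]
  r <- cfg$search_radius_mm
  Tm <- surface$triangles
  V <- surface$vertices
  # candidate filter: AABB within r of p
  cand <- integer()
  for (i in seq_len(nrow(Tm))) {
    tri <- V[Tm[i, ], , drop = FALSE]
    lo <- apply(tri, 2L, min); hi <- apply(tri, 2L, max)
    gap <- pmax(lo - p, p - hi, 0)
    if (sum(gap^2) <= r^2) cand <- c(cand, i)
  }
  if (!length(cand)) return(NA_integer_)
  L <- sqrt(sum((p - q)^2))
  best <- NA_integer_; best_d <- Inf
  if (L > 0) {
    d <- (p - q) / L
    for (i in cand) {
      hit <- moller_trumbore(q, d, V[Tm[i, ], , drop = FALSE])
      if (hit$hit && hit$t <= L + cfg$ray_epsilon_mm) {
        hp <- q + hit$t * d
        dd <- sum((hp - p)^2)
        if (dd < best_d - 1e-15 || (abs(dd - best_d) <= 1e-15 &&
                                    (is.na(best) || i < best))) {
          best <- i; best_d <- dd
        }
      }
    }
    if (!is.na(best)) return(best)
  }
  best <- NA_integer_; best_d <- Inf
  for (i in cand) {
    tri <- V[Tm[i, ], , drop = FALSE]
    dd <- cortiparcel:::point_triangle_sqdist(p, tri[1, , drop = FALSE],
                                             tri[2, , drop = FALSE],
                                             tri[3, , drop = FALSE])
    if (dd < best_d) { best <- i; best_d <- dd }
  }
  if (best_d <= r^2) best else NA_integer_
}

# Brute-force maximal cliques by full subset enumeration (n <= 20).
oracle_max_cliques <- function(vertices, edges) {
  n <- length(vertices)
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    ia <- match(edges[, 1L], vertices)
    ib <- match(edges[, 2L], vertices)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  subsets <- lapply(seq_len(2^n - 1L), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2L) return(length(s) == 1L)
    all(adj[t(utils::combn(s, 2L))])
  }, TRUE)
  cl <- subsets[is_clique]
  maximal <- vapply(cl, function(s) {
    !any(vapply(setdiff(seq_len(n), s), function(v) all(adj[v, s]), TRUE))
  }, TRUE)
  out <- lapply(cl[maximal], function(s) sort(vertices[s]))
  sizes <- vapply(out, length, 1L)
  key <- vapply(out, function(v) paste(sprintf("%09d", v), collapse = ""), "")
  out[order(-sizes, key)]
}
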