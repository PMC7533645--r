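## Synthetic cohort generator.
##
## Emulates the inputs the pipeline consumes in the wild with a fully known
## ground truth: a labeled icosphere "cortex" shared by all subjects, a
## bundle atlas whose fibers run between ground-truth cortical footprints,
## and per-subject tractograms (Gaussian point jitter, random orientation
## flips, rejection-sampled distractor fibers far from every atlas bundle).
##
## Footprint geometry is arranged so the expected sub-parcel support equals
## the ground-truth footprint: fiber endpoints sit at the barycenters of a
## sampling core (the per-footprint cluster eroded by two vertex-rings), and
## the footprint is that core dilated back by one ring — exactly the support
## the accumulation rule produces in the noise-free limit. The two-ring
## margin keeps jittered support inside its own cluster, so footprints of
## different bundles within a region stay disjoint in probability space
## unless an overlap fraction is explicitly requested.

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit sub-seed derivation.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

#' Build an icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times, vertices projected to the
#' sphere of the given radius; V = 10 * 4^k + 2.
#'
#' @param subdivisions Subdivision level (>= 0).
#' @param radius Sphere radius in mm.
#' @return List with `vertices` and `triangles`.
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c_ <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  list(vertices = v, triangles = f)
}

#' Generate a labeled spherical cortex
#'
#' Vertices are partitioned into `n_regions` anatomical regions by nearest
#' random unit-vector seed; seed sets are resampled until every region's
#' triangle set is edge-connected and large enough to host footprints.
#'
#' @param subdivisions Icosphere subdivision level.
#' @param n_regions Number of regions (>= 2).
#' @param seed RNG seed.
#' @param radius Sphere radius in mm.
#' @param min_region_triangles Minimum triangles per region.
#' @return A [labeled_surface()] with region codes `R1`, `R2`, ...
#' @export
make_labeled_sphere <- function(subdivisions = 3L, n_regions = 8L, seed = 1L,
                                radius = 100, min_region_triangles = 40L) {
  if (n_regions < 2L) cp_stop("n_regions must be >= 2")
  mesh <- make_icosphere(subdivisions, radius)
  with_seed(seed, {
    for (try in 1:200) {
      dirs <- matrix(stats::rnorm(3L * n_regions), n_regions, 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      sim <- mesh$vertices %*% t(dirs)
      vlab <- max.col(sim, ties.method = "first")
      surf <- labeled_surface(mesh$vertices, mesh$triangles, vlab)
      sizes <- tabulate(surf$triangle_labels, n_regions)
      if (any(sizes < min_region_triangles)) next
      ok <- all(vapply(seq_len(n_regions), function(rg) {
        tris <- which(surf$triangle_labels == rg)
        length(connected_components(surf$triangle_labels, rg, surf)) == 1L &&
          length(tris) >= min_region_triangles
      }, TRUE))
      if (ok) return(surf)
    }
    cp_stop("could not find a connected region partition in 200 attempts")
  })
}

# Multi-source BFS hop distances over edge adjacency, restricted to a
# triangle set; returns assignment to the nearest source (ties: earlier
# source, then earlier discovery).
cluster_triangles <- function(tris, sources, edge_adj) {
  assign <- stats::setNames(rep(NA_integer_, length(tris)), tris)
  frontier <- sources
  assign[as.character(sources)] <- seq_along(sources)
  while (length(frontier)) {
    nxt <- integer()
    for (t in frontier) {
      a <- assign[[as.character(t)]]
      for (nb in edge_adj[[t]]) {
        key <- as.character(nb)
        if (!key %in% names(assign)) next
        if (is.na(assign[[key]])) {
          assign[[key]] <- a
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  assign
}

# K approximately farthest-point seeds among a triangle set (BFS hops).
farthest_seeds <- function(tris, k, edge_adj) {
  seeds <- tris[sample.int(length(tris), 1L)]
  while (length(seeds) < k) {
    d <- bfs_hops(tris, seeds, edge_adj)
    far <- names(d)[d == max(d)]
    seeds <- c(seeds, as.integer(far[1L]))
  }
  seeds
}

bfs_hops <- function(tris, sources, edge_adj) {
  d <- stats::setNames(rep(Inf, length(tris)), tris)
  d[as.character(sources)] <- 0
  frontier <- sources
  h <- 0
  while (length(frontier)) {
    h <- h + 1
    nxt <- integer()
    for (t in frontier)
      for (nb in edge_adj[[t]]) {
        key <- as.character(nb)
        if (key %in% names(d) && is.infinite(d[[key]])) {
          d[[key]] <- h
          nxt <- c(nxt, nb)
        }
      }
    frontier <- nxt
  }
  d
}

# Dilate a triangle set by one vertex-ring, clipped to `allowed`.
dilate_ring <- function(tris, vertex_adj, allowed) {
  out <- unique(c(tris, unlist(vertex_adj[tris], use.names = FALSE)))
  sort(intersect(out, allowed))
}

# Erode a triangle set by one vertex-ring.
erode_ring <- function(tris, vertex_adj) {
  sort(tris[vapply(tris, function(t) all(vertex_adj[[t]] %in% tris), TRUE)])
}

#' Generate a synthetic bundle atlas with ground-truth footprints
#'
#' Each anatomical region is split into disjoint clusters (one per requested
#' footprint); the sampling core of a footprint is the cluster eroded by two
#' vertex-rings, and the ground-truth footprint is that core dilated back by
#' one ring. Footprints are paired off at random into bundles; fibers are
#' interior arcs between barycenters of core triangles (cycled in shuffled
#' order so the whole core is covered), resampled to 21 points.
#'
#' @param surface A [labeled_surface()] from [make_labeled_sphere()].
#' @param footprints_per_region Integer vector of candidate footprint counts;
#'   each region draws its count from it (recycled/sampled).
#' @param fibers_per_bundle Fibers per atlas bundle.
#' @param seed RNG seed.
#' @param threshold_mm Per-bundle classification threshold. Default 6 mm,
#'   the scale used by published SWM/DWM bundle atlases; must sit well above
#'   the max corresponding-point displacement induced by the jitter model
#'   (~4.3 sigma for 21 points at the 99th percentile).
#' @param overlap_fraction If > 0, the first region with >= 2 footprints gets
#'   its second footprint rebuilt to share at least this fraction of the
#'   first footprint's sampling core (merge-recovery testing).
#' @param arc_depth Fractional depth the fiber arcs dip below the surface.
#' @return List with `atlas` (a [bundle_atlas()]) and `ground_truth`.
#' @export
make_synthetic_atlas <- function(surface, footprints_per_region = 2:4,
                                 fibers_per_bundle = 64L, seed = 1L,
                                 threshold_mm = 6, overlap_fraction = 0,
                                 arc_depth = 0.3) {
  regions <- sort(unique(surface$triangle_labels))
  region_codes <- region_name(surface, regions)
  with_seed(seed, {
    cores <- list()     # sampling cores (eroded)
    foots <- list()     # ground-truth footprints (core + one ring)
    foot_region <- character()
    for (ri in seq_along(regions)) {
      rg <- regions[ri]
      tris <- which(surface$triangle_labels == rg)
      k <- if (length(footprints_per_region) == 1L) footprints_per_region
      else sample(footprints_per_region, 1L)
      # retry seed placement, then degrade k, before giving up: every
      # footprint core (cluster eroded by one vertex-ring) must keep >= 3
      # triangles so endpoints have somewhere to land
      found <- NULL
      while (is.null(found) && k >= 1L) {
        for (attempt in 1:20) {
          seeds <- farthest_seeds(tris, k, surface$edge_adj)
          cl <- cluster_triangles(tris, seeds, surface$edge_adj)
          cand_cores <- lapply(seq_len(k), function(ki) {
            cluster <- as.integer(names(cl)[!is.na(cl) & cl == ki])
            erode_ring(erode_ring(cluster, surface$vertex_adj),
                       surface$vertex_adj)
          })
          if (all(vapply(cand_cores, length, 1L) >= 8L)) {
            found <- list(cl = cl, cores = cand_cores)
            break
          }
        }
        if (is.null(found)) k <- k - 1L
      }
      if (is.null(found))
        cp_stop(paste("footprint core too small in region %s;",
                      "increase mesh subdivisions or reduce footprints"),
                region_codes[ri])
      for (ki in seq_along(found$cores)) {
        cluster <- as.integer(names(found$cl)[!is.na(found$cl) &
                                                found$cl == ki])
        core <- found$cores[[ki]]
        cores[[length(cores) + 1L]] <- core
        foots[[length(foots) + 1L]] <- dilate_ring(core, surface$vertex_adj,
                                                   cluster)
        foot_region <- c(foot_region, region_codes[ri])
      }
    }
    if (overlap_fraction > 0) {
      # rebuild the second footprint of the first doubly-seeded region as a
      # shifted copy of the first, sharing >= overlap_fraction of its core
      tab <- table(foot_region)[unique(foot_region)]
      rg_code <- names(tab)[tab >= 2L][1L]
      if (is.na(rg_code)) cp_stop("no region with >= 2 footprints to overlap")
      ids <- which(foot_region == rg_code)[1:2]
      core_a <- cores[[ids[1L]]]
      drop_n <- max(1L, floor((1 - overlap_fraction) * length(core_a)))
      rg_tris <- which(surface$triangle_labels ==
                         region_label(surface, rg_code))
      ring <- setdiff(dilate_ring(core_a, surface$vertex_adj, rg_tris), core_a)
      core_b <- sort(c(core_a[-seq_len(drop_n)],
                       utils::head(ring, drop_n)))
      cores[[ids[2L]]] <- core_b
      foots[[ids[2L]]] <- dilate_ring(core_b, surface$vertex_adj, rg_tris)
    }
    n_foot <- length(cores)
    if (n_foot < 2L) cp_stop("need at least two footprints")
    perm <- sample.int(n_foot)
    if (n_foot %% 2L == 1L) perm <- perm[-n_foot]   # odd one out unused
    pair_idx <- matrix(perm, ncol = 2L, byrow = TRUE)
    bundles <- list()
    bundle_map <- list()
    pair_counter <- new.env(parent = emptyenv())
    radius <- max(sqrt(rowSums(surface$vertices^2)))
    for (pi in seq_len(nrow(pair_idx))) {
      ia <- pair_idx[pi, 1L]; ib <- pair_idx[pi, 2L]
      ra <- foot_region[ia]; rb <- foot_region[ib]
      pk <- paste(ra, rb, sep = "-")
      idx <- pair_counter[[pk]] %||% 0L
      pair_counter[[pk]] <- idx + 1L
      nm <- sprintf("lh_%s-%s_%d", ra, rb, idx)
      # cycle fiber endpoints over shuffled core triangles so the whole core
      # is covered whenever fibers_per_bundle >= core size (random point
      # within each triangle); uncovered core triangles would otherwise
      # leave holes in the sub-parcel support
      seq_a <- rep_len(sample(cores[[ia]]), fibers_per_bundle)
      seq_b <- rep_len(sample(cores[[ib]]), fibers_per_bundle)
      fibers <- lapply(seq_len(fibers_per_bundle), function(j) {
        p <- triangle_barycenter(surface, seq_a[j])
        q <- triangle_barycenter(surface, seq_b[j])
        interior_arc(p, q, arc_depth)
      })
      bundles[[length(bundles) + 1L]] <-
        bundle(nm, fibers, threshold_mm,
               region_start = ra, region_end = rb, hemisphere = "left")
      bundle_map[[nm]] <- c(footprint_start = ia, footprint_end = ib)
    }
    unused <- if (n_foot %% 2L == 1L) setdiff(seq_len(n_foot), perm) else integer()
    gt <- structure(list(
      footprints = foots, cores = cores, footprint_region = foot_region,
      bundle_map = bundle_map, unused_footprints = unused,
      params = list(seed = seed, threshold_mm = threshold_mm,
                    fibers_per_bundle = fibers_per_bundle,
                    overlap_fraction = overlap_fraction,
                    arc_depth = arc_depth)
    ), class = "ground_truth")
    list(atlas = bundle_atlas(bundles), ground_truth = gt)
  })
}

# Barycenter of one triangle. Atlas fiber endpoints sit at barycenters so
# that subject jitter (sigma << triangle inradius) almost never relocates an
# endpoint into a neighboring triangle: the realized sub-parcel support then
# matches the noise-free ground-truth footprint.
triangle_barycenter <- function(surface, t) {
  colMeans(surface$vertices[surface$triangles[t, ], , drop = FALSE])
}

# 21-point arc from p to q dipping into the sphere interior: spherical
# interpolation of directions with a sin-profile radius dip, then arc-length
# resampling (endpoints preserved exactly).
interior_arc <- function(p, q, depth = 0.3, n_dense = 41L) {
  rp <- sqrt(sum(p^2)); rq <- sqrt(sum(q^2))
  u <- p / rp; v <- q / rq
  d <- max(-1, min(1, sum(u * v)))
  ang <- acos(d)
  s <- seq(0, 1, length.out = n_dense)
  dirs <- if (ang < 1e-8) {
    matrix(u, n_dense, 3L, byrow = TRUE)
  } else {
    w1 <- sin((1 - s) * ang) / sin(ang)
    w2 <- sin(s * ang) / sin(ang)
    outer(w1, u) + outer(w2, v)
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- (rp * (1 - s) + rq * s) * (1 - depth * sin(pi * s))
  pts <- dirs * rad
  pts[1L, ] <- p
  pts[n_dense, ] <- q
  resample_streamline(pts, 21L)
}

#' Simulate one subject's tractogram
#'
#' One jittered copy of every atlas fiber (i.i.d. Gaussian point noise,
#' reversed with probability `flip_prob`) plus distractor fibers
#' rejection-sampled to stay farther than every bundle threshold (plus a 1 mm
#' margin) from every atlas fiber in either orientation.
#'
#' @param atlas A [bundle_atlas()].
#' @param gt The `ground_truth` from [make_synthetic_atlas()] (used for the
#'   geometry scale of distractors).
#' @param subject_seed RNG seed for this subject.
#' @param sigma Jitter standard deviation per coordinate, mm.
#' @param flip_prob Probability a fiber is stored reversed.
#' @param distractor_frac Distractor count as a fraction of atlas fibers.
#' @param shuffle Shuffle fiber order (default TRUE).
#' @return A [tractogram()] with attribute `"truth"`: data frame with
#'   `source` (bundle name or `"distractor"`) and `flipped`.
#' @export
simulate_subject <- function(atlas, gt, subject_seed, sigma = 0.5,
                             flip_prob = 0.5, distractor_frac = 0.2,
                             shuffle = TRUE) {
  with_seed(subject_seed, {
    fibers <- list()
    src <- character()
    flipped <- logical()
    for (b in atlas$bundles) {
      for (f in b$fibers) {
        g <- f + matrix(stats::rnorm(63L, 0, sigma), 21L, 3L)
        fl <- stats::runif(1) < flip_prob
        if (fl) g <- reverse_streamline(g)
        fibers[[length(fibers) + 1L]] <- g
        src <- c(src, b$name)
        flipped <- c(flipped, fl)
      }
    }
    n_atlas <- length(fibers)
    n_dis <- round(distractor_frac * n_atlas)
    if (n_dis > 0L) {
      max_thr <- max(vapply(atlas$bundles, function(b) b$threshold_mm, 1))
      atlas_flat <- flatten_fibers(unlist(lapply(atlas$bundles,
                                                 function(b) b$fibers),
                                          recursive = FALSE))
      atlas_flat_rev <- flatten_fibers(
        lapply(unlist(lapply(atlas$bundles, function(b) b$fibers),
                      recursive = FALSE), reverse_streamline))
      radius <- max(sqrt(atlas_flat^2))
      made <- 0L
      guard <- 0L
      while (made < n_dis) {
        guard <- guard + 1L
        if (guard > 100L * n_dis)
          cp_stop("distractor rejection sampling did not converge")
        e1 <- stats::rnorm(3); e1 <- e1 / sqrt(sum(e1^2)) * 0.35 * radius
        e2 <- stats::rnorm(3); e2 <- e2 / sqrt(sum(e2^2)) * 0.25 * radius
        cand <- interior_arc(e1, e2, depth = 0)
        Fc <- matrix(as.numeric(t(cand)), 1L)
        dmin <- sqrt(min(cross_max_sqdist(Fc, atlas_flat),
                         cross_max_sqdist(Fc, atlas_flat_rev)))
        if (dmin <= max_thr + 1) next
        fibers[[length(fibers) + 1L]] <- cand
        src <- c(src, "distractor")
        flipped <- c(flipped, FALSE)
        made <- made + 1L
      }
    }
    ord <- if (shuffle) sample.int(length(fibers)) else seq_along(fibers)
    t <- tractogram(fibers[ord], space = "synthetic")
    attr(t, "truth") <- data.frame(source = src[ord], flipped = flipped[ord],
                                   stringsAsFactors = FALSE)
    t
  })
}

#' Simulate a full synthetic cohort
#'
#' Default parameters are the package's stated test world: an 8-region
#' labeled icosphere (subdivision 4, radius 60 mm), 2-4 disjoint ground-truth
#' footprints per region, 10 subjects, 0.5 mm point jitter, 50% orientation
#' flips, 20% distractors, 6 mm bundle thresholds.
#'
#' @param n_subjects Number of subjects.
#' @param subdivisions,n_regions,radius Passed to [make_labeled_sphere()].
#' @param footprints_per_region,fibers_per_bundle,threshold_mm,overlap_fraction
#'   Passed to [make_synthetic_atlas()].
#' @param sigma,flip_prob,distractor_frac Passed to [simulate_subject()].
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return An object of class `synthetic_cohort`: list with `surface`,
#'   `atlas`, `ground_truth`, `tractograms`, `truth` (per-subject source
#'   tables), `params`.
#' @export
simulate_cohort <- function(n_subjects = 10L, subdivisions = 4L,
                            n_regions = 8L, radius = 100,
                            footprints_per_region = 2:4,
                            fibers_per_bundle = 64L, threshold_mm = 6,
                            overlap_fraction = 0, sigma = 0.5,
                            flip_prob = 0.5, distractor_frac = 0.2,
                            seed = 1L) {
  surface <- make_labeled_sphere(subdivisions, n_regions,
                                 seed = derive_seed(seed, 1L), radius = radius)
  syn <- make_synthetic_atlas(surface, footprints_per_region,
                              fibers_per_bundle,
                              seed = derive_seed(seed, 2L),
                              threshold_mm = threshold_mm,
                              overlap_fraction = overlap_fraction)
  tractograms <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    t <- simulate_subject(syn$atlas, syn$ground_truth,
                          subject_seed = derive_seed(seed, 100L + s),
                          sigma = sigma, flip_prob = flip_prob,
                          distractor_frac = distractor_frac)
    truth[[s]] <- attr(t, "truth")
    attr(t, "truth") <- NULL
    tractograms[[s]] <- t
  }
  structure(list(
    surface = surface, atlas = syn$atlas, ground_truth = syn$ground_truth,
    tractograms = tractograms, truth = truth,
    params = list(n_subjects = n_subjects, subdivisions = subdivisions,
                  n_regions = n_regions, radius = radius,
                  footprints_per_region = footprints_per_region,
                  fibers_per_bundle = fibers_per_bundle,
                  threshold_mm = threshold_mm,
                  overlap_fraction = overlap_fraction, sigma = sigma,
                  flip_prob = flip_prob, distractor_frac = distractor_frac,
                  seed = seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d subjects, %d bundles, ",
                     "%d footprints, %d-triangle mesh\n"),
              length(x$tractograms), length(x$atlas$bundles),
              length(x$ground_truth$footprints), nrow(x$surface$triangles)))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Writes the mesh (OBJ + labels), the atlas (TCK + bundles.tsv), per-subject
#' tractograms (TCK), and the ground truth (JSON).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labeled_surface(cohort$surface, file.path(dir, "mesh.obj"),
                        file.path(dir, "labels.txt"))
  write_bundle_atlas(cohort$atlas, file.path(dir, "atlas"))
  dir.create(file.path(dir, "subjects"), showWarnings = FALSE)
  for (s in seq_along(cohort$tractograms))
    write_tractogram(cohort$tractograms[[s]],
                     file.path(dir, "subjects", sprintf("subject_%03d.tck", s)))
  jsonlite::write_json(
    list(footprints = cohort$ground_truth$footprints,
         cores = cohort$ground_truth$cores,
         footprint_region = cohort$ground_truth$footprint_region,
         bundle_map = cohort$ground_truth$bundle_map,
         params = cohort$params),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
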