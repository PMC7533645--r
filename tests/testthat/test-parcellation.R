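# Step 5 — preliminary sub-parcels, probability maps, density centers,
# merge graph, maximal cliques, greedy merging, hardening.

# Hand-controllable fixture: the 4-region test sphere plus synthetic filtered
# records pointing at chosen triangles.
parcel_fixture <- function() {
  surf <- test_sphere()
  codes <- surf$label_table$name
  tris <- lapply(surf$label_table$label,
                 function(l) which(surf$triangle_labels == l))
  mk_bundle <- function(nm, ra, rb) bundle(
    nm, replicate(2, matrix(seq_len(63), 21, 3), simplify = FALSE),
    threshold_mm = 5, region_start = ra, region_end = rb, hemisphere = "left")
  atlas <- bundle_atlas(list(
    mk_bundle(sprintf("lh_%s-%s_0", codes[1L], codes[2L]), codes[1L], codes[2L]),
    mk_bundle(sprintf("lh_%s-%s_0", codes[3L], codes[4L]), codes[3L], codes[4L])))
  list(surf = surf, atlas = atlas, codes = codes, tris = tris)
}

test_that("count accumulation matches a hand-rolled neighborhood oracle", {
  fx <- parcel_fixture()
  surf <- fx$surf
  set.seed(51)
  bnames <- names(fx$atlas$bundles)
  subjects <- lapply(1:4, function(s) {
    do.call(rbind, lapply(seq_along(bnames), function(bi) {
      b <- fx$atlas$bundles[[bi]]
      rs <- which(surf$triangle_labels == region_label(surf, b$region_start))
      re <- which(surf$triangle_labels == region_label(surf, b$region_end))
      data.frame(fiber_id = 0:9, bundle = bnames[bi],
                 tri_start = sample(rs, 10, TRUE),
                 tri_end = sample(re, 10, TRUE),
                 flipped = FALSE, stringsAsFactors = FALSE)
    }))
  })
  sps <- build_preliminary_subparcels(subjects, fx$atlas, surf)
  expect_identical(length(sps$subparcels), 4L)   # two per bundle
  # independent oracle: accumulate per triangle with plain loops
  for (bi in seq_along(bnames)) {
    b <- fx$atlas$bundles[[bi]]
    for (side in c("start", "end")) {
      lab <- 2L * (bi - 1L) + if (side == "start") 1L else 2L
      region <- region_label(surf, if (side == "start") b$region_start
                             else b$region_end)
      expected <- numeric(nrow(surf$triangles))
      for (df in subjects) {
        hits <- df[df$bundle == bnames[bi],
                   if (side == "start") "tri_start" else "tri_end"]
        for (t in hits) {
          for (nb in c(t, surf$vertex_adj[[t]]))
            if (surf$triangle_labels[nb] == region)
              expected[nb] <- expected[nb] + 1
        }
      }
      sp <- sps$subparcels[[as.character(lab)]]
      expect_identical(sp$tris, which(expected > 0))
      expect_equal(sp$counts, expected[expected > 0])
      expect_identical(sp$region, region_name(surf, region))
    }
  }
})

test_that("three subjects with one fiber at triangle T give N(T) = 3", {
  fx <- parcel_fixture()
  surf <- fx$surf
  b <- fx$atlas$bundles[[1L]]
  rs <- which(surf$triangle_labels == region_label(surf, b$region_start))
  re <- which(surf$triangle_labels == region_label(surf, b$region_end))
  T_ <- rs[10L]
  one <- data.frame(fiber_id = 0L, bundle = names(fx$atlas$bundles)[1L],
                    tri_start = T_, tri_end = re[1L], flipped = FALSE,
                    stringsAsFactors = FALSE)
  sps <- build_preliminary_subparcels(list(one, one, one), fx$atlas, surf)
  sp <- sps$subparcels[["1"]]
  expect_equal(sp$counts[match(T_, sp$tris)], 3)
  # the end triangle's in-region vertex neighbors carry counts too
  nb <- surf$vertex_adj[[T_]]
  nb <- nb[surf$triangle_labels[nb] == surf$triangle_labels[T_]]
  expect_true(all(nb %in% sp$tris))
})

test_that("probability maps normalize, sort, and follow hand arithmetic", {
  fx <- parcel_fixture()
  ntri <- nrow(fx$surf$triangles)
  sps <- cortiparcel:::subparcel_set(list(
    cortiparcel:::new_subparcel(1L, "a", "R1", c(5L, 6L), c(3, 3)),
    cortiparcel:::new_subparcel(2L, "b", "R1", c(6L, 7L), c(1, 4))), ntri)
  pmap <- compute_probability_maps(sps)
  expect_equal(pmap[["5"]]$p, 1)
  expect_equal(pmap[["6"]]$p, c(0.75, 0.25))            # counts 3 and 1
  expect_identical(pmap[["6"]]$labels, c(1L, 2L))
  expect_identical(sort(as.integer(names(pmap))), 5:7)
  for (e in pmap) expect_equal(sum(e$p), 1, tolerance = 1e-9)
  # ties broken by label ascending
  sps2 <- cortiparcel:::subparcel_set(list(
    cortiparcel:::new_subparcel(4L, "a", "R1", 9L, 2),
    cortiparcel:::new_subparcel(2L, "b", "R1", 9L, 2)), ntri)
  expect_identical(compute_probability_maps(sps2)[["9"]]$labels, c(2L, 4L))
})

test_that("size filtering follows the region-mean rule", {
  fx <- parcel_fixture()
  ntri <- nrow(fx$surf$triangles)
  mk <- function(lab, region, n) cortiparcel:::new_subparcel(
    lab, paste0("sp", lab), region, seq_len(n), rep(1, n))
  sps <- cortiparcel:::subparcel_set(
    list(mk(1L, "A", 100L), mk(2L, "A", 100L), mk(3L, "A", 100L)), ntri)
  kept <- remove_small_subparcels(sps, fx$surf, 0.10)
  expect_identical(length(kept$subparcels), 3L)
  sps2 <- cortiparcel:::subparcel_set(
    list(mk(1L, "A", 100L), mk(2L, "A", 100L), mk(3L, "A", 5L)), ntri)
  kept2 <- remove_small_subparcels(sps2, fx$surf, 0.10)
  expect_identical(names(kept2$subparcels), c("1", "2"))  # 5 < 0.10 * 68.33
  # size_thr -> 0 limit removes nothing
  kept3 <- remove_small_subparcels(sps2, fx$surf, 1e-9)
  expect_identical(length(kept3$subparcels), 3L)
  # region_fraction mode measures against the region triangle count
  codes <- fx$codes
  n_r1 <- length(fx$tris[[1L]])
  sps3 <- cortiparcel:::subparcel_set(
    list(mk(1L, codes[1L], as.integer(ceiling(0.2 * n_r1))),
         mk(2L, codes[1L], 2L)), ntri)
  kept4 <- remove_small_subparcels(sps3, fx$surf, 0.10, "region_fraction")
  expect_identical(names(kept4$subparcels), "1")
})

test_that("density centers threshold probabilities and shrink monotonically", {
  fx <- parcel_fixture()
  ntri <- nrow(fx$surf$triangles)
  set.seed(52)
  sps <- cortiparcel:::subparcel_set(lapply(1:4, function(l)
    cortiparcel:::new_subparcel(l, paste0("sp", l), "A",
                                sample.int(60L, 30L),
                                stats::rexp(30L) + 0.1)), ntri)
  pmap <- compute_probability_maps(sps)
  # single sub-parcel: dc = full support at any threshold
  solo <- cortiparcel:::subparcel_set(
    list(cortiparcel:::new_subparcel(9L, "s", "A", 1:5, rep(2, 5))), ntri)
  dc_solo <- compute_density_centers(compute_probability_maps(solo), 0.30)
  expect_identical(dc_solo[["9"]], 1:5)
  # threshold excludes p below it
  duo <- cortiparcel:::subparcel_set(list(
    cortiparcel:::new_subparcel(1L, "a", "A", 1L, 1),
    cortiparcel:::new_subparcel(2L, "b", "A", 1L, 3)), ntri)
  dc_duo <- compute_density_centers(compute_probability_maps(duo), 0.30)
  expect_identical(dc_duo[["1"]], integer())               # p = 0.25 < 0.30
  expect_identical(dc_duo[["2"]], 1L)
  # monotone shrinkage across a threshold sweep
  prev <- NULL
  for (thr in c(0.05, 0.15, 0.25, 0.35, 0.5)) {
    dcs <- compute_density_centers(pmap, thr)
    if (!is.null(prev))
      for (l in names(dcs)) expect_true(all(dcs[[l]] %in% prev[[l]]))
    prev <- dcs
  }
})

test_that("idc follows Eq. 1 set arithmetic", {
  expect_equal(compute_idc(1:4, 1:4), 1)
  expect_equal(compute_idc(1:4, 9:12), 0)
  expect_equal(compute_idc(1:4, 3:8), 0.5)       # |{3,4}| / min(4, 6)
  expect_equal(compute_idc(integer(), 1:3), 0)
  set.seed(53)
  for (i in 1:50) {
    a <- sample.int(40L, sample.int(20L, 1L))
    b <- sample.int(40L, sample.int(20L, 1L))
    v <- compute_idc(a, b)
    expect_identical(v, compute_idc(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, sum(!is.na(match(unique(a), unique(b)))) /
                   min(length(unique(a)), length(unique(b))))
  }
})

test_that("merge graph uses inclusive thresholds and drops isolated vertices", {
  dcs <- list(`1` = 1:4, `2` = 3:6, `3` = 101:104)
  # idc(1,2) = 2/4 = 0.5 exactly: edge present at idc_thr = 0.5 (>=)
  g <- build_merge_graph(c(1L, 2L, 3L), dcs, 0.5)
  expect_identical(g$vertices, c(1L, 2L))
  expect_identical(g$edges, cbind(1L, 2L))
  g2 <- build_merge_graph(c(1L, 2L, 3L), dcs, 0.51)
  expect_identical(g2$vertices, integer())
  # three mutually overlapping sub-parcels form K3
  dcs3 <- list(`1` = 1:6, `2` = 4:9, `3` = c(1:2, 5:7))
  g3 <- build_merge_graph(1:3, dcs3, 0.3)
  expect_identical(nrow(g3$edges), 3L)
})

test_that("maximal cliques match brute-force enumeration", {
  tri_g <- structure(list(vertices = 1:3, edges = rbind(c(1L, 2L), c(1L, 3L),
                                                        c(2L, 3L))),
                     class = "merge_graph")
  expect_identical(enumerate_maximal_cliques(tri_g), list(1:3))
  path_g <- structure(list(vertices = 1:3, edges = rbind(c(1L, 2L),
                                                         c(2L, 3L))),
                      class = "merge_graph")
  expect_identical(enumerate_maximal_cliques(path_g), list(1:2, 2:3))
  set.seed(54)
  for (i in 1:25) {
    n <- sample(4:10, 1L)
    verts <- sort(sample.int(50L, n))
    all_pairs <- t(utils::combn(verts, 2L))
    edges <- all_pairs[runif(nrow(all_pairs)) < 0.4, , drop = FALSE]
    connected <- sort(unique(as.integer(edges)))
    g <- structure(list(vertices = connected, edges = edges),
                   class = "merge_graph")
    expect_identical(enumerate_maximal_cliques(g),
                     oracle_max_cliques(connected, edges))
  }
})

test_that("greedy clique merging consumes members in size order", {
  ntri <- 200L
  mk <- function(lab, tris) cortiparcel:::new_subparcel(
    lab, paste0("sp", lab), "A", tris, rep(1, length(tris)))
  sps <- cortiparcel:::subparcel_set(
    list(mk(1L, 1:10), mk(2L, 8:14), mk(3L, 12:20), mk(4L, 19:25)), ntri)
  # single clique {1,2,3}: counts sum per triangle
  out <- merge_cliques(sps, list(c(1L, 2L, 3L)))
  expect_identical(names(out$sps$subparcels), c("4", "5"))
  merged <- out$sps$subparcels[["5"]]
  expect_identical(merged$tris, 1:20)
  expect_equal(merged$counts[8:10], rep(2, 3))     # overlap of sp1 and sp2
  expect_identical(merged$name, "sp1+sp2+sp3")
  # cliques {1,2,3} then {2,4}: 2 consumed, {4} alone stays unmerged
  out2 <- merge_cliques(sps, list(c(1L, 2L, 3L), c(2L, 4L)))
  expect_identical(names(out2$sps$subparcels), c("4", "5"))
  expect_identical(nrow(out2$merges), 1L)
  # no cliques: identity
  out3 <- merge_cliques(sps, list())
  expect_identical(out3$sps$subparcels, sps$subparcels)
})

test_that("hardening takes the per-triangle argmax and leaves gaps NA", {
  ntri <- 50L
  sps <- cortiparcel:::subparcel_set(list(
    cortiparcel:::new_subparcel(1L, "a", "A", c(1L, 2L), c(3, 1)),
    cortiparcel:::new_subparcel(2L, "b", "A", c(2L, 3L), c(1, 2))), ntri)
  pmap <- compute_probability_maps(sps)
  parc <- harden(pmap, sps)
  expect_identical(parc$labels[1L], 1L)
  expect_identical(parc$labels[2L], 1L)   # 0.75 vs 0.25
  expect_identical(parc$labels[3L], 2L)
  expect_true(all(is.na(parc$labels[4:50])))
  # exhaustive argmax check
  for (k in names(pmap)) {
    e <- pmap[[k]]
    expect_identical(parc$labels[as.integer(k)],
                     e$labels[which.max(e$p)])
  }
})

test_that("probability maps stay normalized through the full chain", {
  res <- small_run()
  for (e in res$pmap) expect_equal(sum(e$p), 1, tolerance = 1e-9)
  # final sub-parcel supports stay inside their anatomical region
  surf <- small_cohort()$surface
  for (sp in res$sps$subparcels)
    expect_true(all(surf$triangle_labels[sp$tris] ==
                      region_label(surf, sp$region)))
})
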