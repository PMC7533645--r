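# Domain types, file round trips, adjacency and resampling.

test_that("TCK round trip preserves coordinates and fiber order", {
  set.seed(1)
  fibers <- lapply(c(5L, 21L, 3L), function(n) matrix(rnorm(n * 3, sd = 40), n, 3))
  t <- tractogram(fibers, space = "MNI")
  path <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(t, path)
  t2 <- read_tractogram(path)
  expect_length(t2$streamlines, 3L)
  for (i in 1:3)
    expect_lt(max(abs(t2$streamlines[[i]] - fibers[[i]])), 1e-5)
})

test_that("TCK with 10 fibers of 21 points reads back as 10 streamlines", {
  set.seed(2)
  fibers <- replicate(10, matrix(rnorm(63), 21, 3), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".tck")
  write_tractogram(tractogram(fibers), path)
  t <- read_tractogram(path)
  expect_length(t$streamlines, 10L)
  expect_true(all(vapply(t$streamlines, nrow, 1L) == 21L))
})

test_that("TRK round trip preserves coordinates and rejects bad headers", {
  set.seed(3)
  fibers <- replicate(4, matrix(rnorm(30, sd = 30), 10, 3), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".trk")
  write_tractogram(tractogram(fibers), path)
  t2 <- read_tractogram(path)
  for (i in 1:4)
    expect_lt(max(abs(t2$streamlines[[i]] - fibers[[i]])), 1e-5)
  # corrupt the id_string: the error must name the offending field
  raw <- readBin(path, "raw", file.info(path)$size)
  raw[1:5] <- charToRaw("WRONG")
  writeBin(raw, path)
  expect_error(read_tractogram(path), "id_string",
               class = "cortiparcel_format_error")
})

test_that("malformed TCK headers and empty streamline records are rejected", {
  path <- withr::local_tempfile(fileext = ".tck")
  writeLines(c("not mrtrix", "END"), path)
  expect_error(read_tractogram(path), "mrtrix",
               class = "cortiparcel_format_error")
  # hand-craft a file containing an empty record (two adjacent separators)
  hdr <- "mrtrix tracks\ndatatype: Float32LE\n"
  off <- nchar(hdr)
  repeat {
    file_line <- sprintf("file: . %d\nEND\n", off)
    if (nchar(hdr) + nchar(file_line) == off) break
    off <- nchar(hdr) + nchar(file_line)
  }
  con <- file(path, "wb")
  writeChar(paste0(hdr, file_line), con, eos = NULL)
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(NaN, NaN, NaN), c(NaN, NaN, NaN),
               c(2, 0, 0), c(3, 0, 0), c(Inf, Inf, Inf))
  writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_tractogram(path), "empty",
               class = "cortiparcel_format_error")
})

test_that("tractogram constructor enforces the streamline invariants", {
  expect_error(tractogram(list(matrix(0, 1, 3))), "fewer than 2")
  expect_error(tractogram(list(matrix(c(0, NA), 2, 3))), "non-finite")
  expect_error(tractogram(list(matrix(0, 2, 2))), "n x 3")
})

test_that("resampling places points at equal arc length", {
  s <- cbind(seq(0, 20, length.out = 5), 0, 0)
  r <- resample_streamline(s, 21L)
  expect_equal(r[, 1L], 0:20, tolerance = 1e-9)
  expect_equal(r[, 2:3], matrix(0, 21, 2), tolerance = 1e-12)
  # idempotence on an already-equidistant 21-point fiber
  expect_equal(resample_streamline(r, 21L), r, tolerance = 1e-6)
  # L-shaped polyline, total length 10, n = 5 -> arc lengths 0, 2.5, ..., 10
  L <- rbind(c(0, 0, 0), c(6, 0, 0), c(6, 4, 0))
  r5 <- resample_streamline(L, 5L)
  expect_equal(r5, rbind(c(0, 0, 0), c(2.5, 0, 0), c(5, 0, 0),
                         c(6, 1.5, 0), c(6, 4, 0)), tolerance = 1e-9)
  expect_error(resample_streamline(matrix(1, 3, 3), 5L), "degenerate")
})

test_that("resampling preserves endpoints exactly and arc length to 0.5%", {
  set.seed(4)
  for (rep in 1:20) {
    # smooth random curve densely sampled (arc-length preservation is a
    # property of resolved geometry, not of sub-resolution zigzag)
    n <- sample(60:120, 1L)
    u <- seq(0, 1, length.out = n)
    a <- rnorm(3, sd = 30); b <- rnorm(3, sd = 30); c_ <- rnorm(3, sd = 15)
    s <- cbind(a[1] * u + c_[1] * sin(2 * u), b[2] * u + c_[2] * cos(2 * u),
               a[3] * u^2 + c_[3] * u)
    r <- resample_streamline(s, 21L)
    expect_identical(r[1L, ], s[1L, ])
    expect_identical(r[21L, ], s[n, ])
    len_in <- sum(sqrt(rowSums(diff(s)^2)))
    len_out <- sum(sqrt(rowSums(diff(r)^2)))
    expect_lt(abs(len_out - len_in) / len_in, 0.005)
  }
})

test_that("triangle labels follow majority with lowest-vertex tie-break", {
  tri <- matrix(c(1L, 2L, 3L), 1L)
  expect_identical(derive_triangle_labels(tri, c(5L, 5L, 9L)), 5L)
  expect_identical(derive_triangle_labels(tri, c(9L, 5L, 5L)), 5L)
  expect_identical(derive_triangle_labels(tri, c(5L, 9L, 5L)), 5L)
  expect_identical(derive_triangle_labels(tri, c(5L, 5L, 5L)), 5L)
  # all three differ on vertices (10, 4, 7): vertex 4 is lowest -> its label
  tri2 <- matrix(c(10L, 4L, 7L), 1L)
  labs <- integer(10)
  labs[c(10L, 4L, 7L)] <- c(3L, 8L, 2L)
  expect_identical(derive_triangle_labels(tri2, labs), 8L)
})

test_that("uniform vertex labels give uniform triangle labels", {
  surf <- tiny_icosahedron(7L)
  expect_true(all(surf$triangle_labels == 7L))
})

test_that("vertex- and edge-adjacency behave per definition", {
  # two triangles sharing exactly one vertex
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  tr <- rbind(c(1L, 2L, 3L), c(1L, 4L, 5L))
  surf <- labeled_surface(v, tr, rep(1L, 5L))
  expect_identical(surf$vertex_adj[[1L]], 2L)
  expect_identical(surf$vertex_adj[[2L]], 1L)
  expect_identical(surf$edge_adj[[1L]], integer())
  expect_identical(surf$edge_adj[[2L]], integer())
})

test_that("adjacency is symmetric, excludes self, and edge subset of vertex", {
  surf <- test_sphere()
  nt <- nrow(surf$triangles)
  for (i in seq_len(nt)) {
    expect_false(i %in% surf$vertex_adj[[i]])
    expect_true(all(surf$edge_adj[[i]] %in% surf$vertex_adj[[i]]))
    for (j in surf$edge_adj[[i]]) expect_true(i %in% surf$edge_adj[[j]])
    for (j in surf$vertex_adj[[i]]) expect_true(i %in% surf$vertex_adj[[j]])
  }
})

test_that("icosphere edge adjacency matches brute-force edge sharing", {
  mesh <- make_icosphere(3L, radius = 1)   # 642 vertices, 1280 triangles
  expect_identical(nrow(mesh$vertices), 642L)
  surf <- labeled_surface(mesh$vertices, mesh$triangles,
                          rep(1L, nrow(mesh$vertices)))
  # independent oracle: count shared vertices through vertex incidence
  nt <- nrow(surf$triangles)
  incident <- split(rep(seq_len(nt), 3L), as.vector(surf$triangles))
  for (i in sample.int(nt, 200L)) {
    partners <- table(unlist(incident[as.character(surf$triangles[i, ])]))
    partners <- partners[names(partners) != as.character(i)]
    edge_nb <- sort(as.integer(names(partners)[partners >= 2L]))
    expect_identical(surf$edge_adj[[i]], edge_nb)
  }
  expect_true(all(lengths(surf$edge_adj) == 3L))
})

test_that("OBJ + label text round trip, with count mismatch rejected", {
  surf <- test_sphere()
  mesh_path <- withr::local_tempfile(fileext = ".obj")
  lab_path <- withr::local_tempfile(fileext = ".txt")
  write_labeled_surface(surf, mesh_path, lab_path)
  surf2 <- read_labeled_surface(mesh_path, lab_path)
  expect_equal(surf2$vertices, surf$vertices, tolerance = 1e-6)
  expect_identical(surf2$triangles, surf$triangles)
  expect_identical(surf2$vertex_labels, surf$vertex_labels)
  expect_identical(surf2$triangle_labels, surf$triangle_labels)
  writeLines(as.character(surf$vertex_labels[-1L]), lab_path)
  expect_error(read_labeled_surface(mesh_path, lab_path), "does not match")
})

test_that("GIfTI surfaces and label arrays are read in all encodings", {
  surf <- test_sphere()
  b64 <- function(x, type) jsonlite::base64_enc(
    writeBin(if (type == "f") as.numeric(x) else as.integer(x), raw(),
             size = 4L, endian = "little"))
  vdat <- b64(as.numeric(t(surf$vertices)), "f")
  tdat0 <- as.integer(t(surf$triangles)) - 1L
  tgz <- jsonlite::base64_enc(memCompress(
    writeBin(tdat0, raw(), size = 4L, endian = "little"), "gzip"))
  da <- function(intent, dtype, enc, dim0, dim1, payload) sprintf(
    paste0('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
           'Dimensionality="2" Dim0="%d" Dim1="%d" Encoding="%s" Endian="LittleEndian">',
           '<Data>%s</Data></DataArray>'),
    intent, dtype, dim0, dim1, enc, payload)
  gii <- paste0('<?xml version="1.0"?><GIFTI Version="1.0">',
                da("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   "Base64Binary", nrow(surf$vertices), 3L, vdat),
                da("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   "GZipBase64Binary", nrow(surf$triangles), 3L, tgz),
                '</GIFTI>')
  gii_path <- withr::local_tempfile(fileext = ".surf.gii")
  writeLines(gii, gii_path)
  lab_path <- withr::local_tempfile(fileext = ".label.gii")
  write_gifti_labels(surf$vertex_labels, surf$label_table, lab_path)
  surf2 <- read_labeled_surface(gii_path, lab_path)
  expect_equal(surf2$vertices, surf$vertices, tolerance = 1e-5)
  expect_identical(surf2$triangles, surf$triangles)
  expect_identical(surf2$vertex_labels, surf$vertex_labels)
  expect_identical(surf2$label_table$name, surf$label_table$name)
})

test_that("pipeline config files round trip and validate", {
  cfg <- pipeline_config(size_thr = 0.2, dc_thr = 0.25, idc_thr = 0.3,
                         rng_seed = 17L, size_mode = "region_fraction")
  path <- withr::local_tempfile(fileext = ".ini")
  write_pipeline_config(cfg, path)
  cfg2 <- read_pipeline_config(path)
  expect_equal(cfg2[names(cfg2) != "rng_seed"], cfg[names(cfg) != "rng_seed"],
               tolerance = 1e-12)
  expect_identical(cfg2$rng_seed, 17L)
  expect_error(pipeline_config(size_thr = 0), "in \\(0, 1\\)")
  expect_error(pipeline_config(dc_thr = 1), "in \\(0, 1\\)")
})
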