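## TCK (MRtrix) and TRK (TrackVis) streamline container I/O.
##
## Both dialects store float32 point triples in mm-scale coordinates. The
## readers here are deliberately strict about the few header fields that the
## formats require, and name the offending field on failure. TRK files are
## written with unit voxel size, identity vox-to-ras and RAS voxel order, so
## voxel-mm coordinates coincide with world mm; the reader refuses files whose
## header implies a non-trivial voxel scaling (registration is out of scope).

#' Read / write a tractogram file
#'
#' The dialect is chosen from the file extension: `.tck` (MRtrix) or `.trk`
#' (TrackVis). Round-tripping preserves point coordinates to float32
#' precision (<= 1e-5 mm at brain-scale magnitudes) and fiber order.
#'
#' @param path File path ending in `.tck` or `.trk`.
#' @param space Coordinate-space tag attached to the returned tractogram.
#' @return `read_tractogram()` returns a [tractogram()].
#' @export
read_tractogram <- function(path, space = "unknown") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = read_tck(path, space),
         trk = read_trk(path, space),
         cp_stop("unsupported streamline format '.%s' (use .tck or .trk)", ext))
}

#' @rdname read_tractogram
#' @param t A [tractogram()].
#' @export
write_tractogram <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = write_tck(t, path),
         trk = write_trk(t, path),
         cp_stop("unsupported streamline format '.%s' (use .tck or .trk)", ext))
  invisible(path)
}

## ---- TCK ------------------------------------------------------------------

read_tck <- function(path, space = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks"))
    cp_stop("TCK header: first line is not 'mrtrix tracks'",
            class = "cortiparcel_format_error")
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln))
      cp_stop("TCK header: missing END line",
              class = "cortiparcel_format_error")
    if (identical(trimws(ln), "END")) break
    hdr <- c(hdr, ln)
  }
  kv <- strsplit(hdr, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"), ""))
  get_field <- function(k) {
    i <- which(keys == k)
    if (!length(i))
      cp_stop("TCK header: missing required field '%s'", k,
              class = "cortiparcel_format_error")
    vals[[i[1L]]]
  }
  datatype <- get_field("datatype")
  endian <- if (grepl("LE$", datatype)) "little" else "big"
  fsize <- if (grepl("^Float32", datatype)) 4L
           else if (grepl("^Float64", datatype)) 8L
           else cp_stop("TCK header: unsupported datatype '%s'", datatype,
                        class = "cortiparcel_format_error")
  offset <- suppressWarnings(as.integer(sub("^\\.\\s+", "", get_field("file"))))
  if (is.na(offset))
    cp_stop("TCK header: malformed 'file' field",
            class = "cortiparcel_format_error")
  seek(con, offset)
  n_bytes <- file.info(path)$size - offset
  raw_vals <- readBin(con, "double", n = n_bytes %/% fsize, size = fsize,
                      endian = endian)
  if (length(raw_vals) %% 3L != 0L)
    cp_stop("TCK data: point stream is not a whole number of triples",
            class = "cortiparcel_format_error")
  pts <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(pts[, 1L])
  is_end <- is.infinite(pts[, 1L])
  if (!any(is_end))
    cp_stop("TCK data: missing end-of-file triple",
            class = "cortiparcel_format_error")
  pts <- pts[seq_len(which(is_end)[1L] - 1L), , drop = FALSE]
  is_sep <- is.nan(pts[, 1L])
  if (length(is_sep) &&
      (is_sep[1L] || is_sep[length(is_sep)] ||
       any(is_sep[-1L] & is_sep[-length(is_sep)])))
    cp_stop("TCK data: empty streamline record",
            class = "cortiparcel_format_error")
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)]))
  keep <- !is_sep
  rows <- split(which(keep), grp[keep])
  streamlines <- lapply(rows, function(i) pts[i, , drop = FALSE])
  tractogram(unname(streamlines), space = space)
}

write_tck <- function(t, path) {
  n <- length(t$streamlines)
  hdr_lines <- c("mrtrix tracks",
                 "datatype: Float32LE",
                 sprintf("count: %d", n),
                 "cortiparcel_space: %s")
  hdr_lines[4L] <- sprintf("cortiparcel_space: %s", t$space)
  # 'file: . <offset>' must state its own byte offset; fix by two-pass sizing
  base <- paste0(paste(hdr_lines, collapse = "\n"), "\n")
  offset <- nchar(base, type = "bytes")
  repeat {
    file_line <- sprintf("file: . %d\nEND\n", offset)
    total <- nchar(base, type = "bytes") + nchar(file_line, type = "bytes")
    if (total == offset) break
    offset <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(base, file_line), con, eos = NULL)
  for (i in seq_along(t$streamlines)) {
    if (i > 1L) writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(t$streamlines[[i]])), con, size = 4L,
             endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

## ---- TRK ------------------------------------------------------------------

read_trk <- function(path, space = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1000L)
  if (length(hdr_raw) < 1000L)
    cp_stop("TRK header: file shorter than the 1000-byte header",
            class = "cortiparcel_format_error")
  id <- rawToChar(hdr_raw[1:5])
  if (!identical(id, "TRACK"))
    cp_stop("TRK header: id_string is '%s', expected 'TRACK'", id,
            class = "cortiparcel_format_error")
  rd <- function(what, off, n, size) {
    readBin(hdr_raw[(off + 1L):length(hdr_raw)], what, n = n, size = size,
            endian = "little")
  }
  hdr_size <- rd("integer", 996L, 1L, 4L)
  if (hdr_size != 1000L)
    cp_stop("TRK header: hdr_size is %d, expected 1000 (wrong endianness?)",
            hdr_size, class = "cortiparcel_format_error")
  voxel_size <- rd("double", 12L, 3L, 4L)
  n_scalars <- rd("integer", 36L, 1L, 2L)
  n_properties <- rd("integer", 238L, 1L, 2L)
  if (n_scalars < 0L || n_scalars > 10L)
    cp_stop("TRK header: n_scalars out of range (%d)", n_scalars,
            class = "cortiparcel_format_error")
  if (any(abs(voxel_size - 1) > 1e-6) && any(voxel_size != 0))
    cp_stop("TRK header: voxel_size %s != 1; voxel-scaled files are not supported",
            paste(signif(voxel_size, 4), collapse = "x"),
            class = "cortiparcel_format_error")
  n_count <- rd("integer", 988L, 1L, 4L)
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!length(np)) break
    if (np < 1L)
      cp_stop("TRK data: record with point count %d", np,
              class = "cortiparcel_format_error")
    vals <- readBin(con, "double", n = np * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (length(vals) < np * (3L + n_scalars))
      cp_stop("TRK data: truncated streamline record",
              class = "cortiparcel_format_error")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    if (n_properties > 0L)
      readBin(con, "double", n = n_properties, size = 4L, endian = "little")
    streamlines[[length(streamlines) + 1L]] <- m[, 1:3, drop = FALSE]
  }
  if (n_count > 0L && n_count != length(streamlines))
    cp_stop("TRK header: n_count %d but %d records read", n_count,
            length(streamlines), class = "cortiparcel_format_error")
  tractogram(streamlines, space = space)
}

write_trk <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000L)
  put <- function(hdr, bytes, off) {
    hdr[(off + 1L):(off + length(bytes))] <- bytes
    hdr
  }
  hdr <- put(hdr, charToRaw("TRACK"), 0L)
  hdr <- put(hdr, writeBin(c(1L, 1L, 1L), raw(), size = 2L, endian = "little"), 6L)   # dim
  hdr <- put(hdr, writeBin(c(1, 1, 1), raw(), size = 4L, endian = "little"), 12L)     # voxel_size
  # identity vox_to_ras (rows of 4x4)
  eye <- c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1)
  hdr <- put(hdr, writeBin(eye, raw(), size = 4L, endian = "little"), 440L)
  hdr <- put(hdr, charToRaw("RAS"), 948L)                                             # voxel_order
  hdr <- put(hdr, writeBin(length(t$streamlines), raw(), size = 4L,
                           endian = "little"), 988L)                                  # n_count
  hdr <- put(hdr, writeBin(2L, raw(), size = 4L, endian = "little"), 992L)            # version
  hdr <- put(hdr, writeBin(1000L, raw(), size = 4L, endian = "little"), 996L)         # hdr_size
  writeBin(hdr, con)
  for (s in t$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
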