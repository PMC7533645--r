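## Minimal NIfTI-1 support for volumetric label images.
##
## Only what the evaluation stage needs: a 3-D integer label array plus the
## voxel-to-world affine. Supports .nii and .nii.gz, little- and big-endian
## files, integer and float datatypes; the affine comes from the sform rows
## when sform_code > 0, else from qform-free pixdim scaling.

#' In-memory labeled volume
#'
#' @param data 3-D array of integer labels (0 = background).
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) cp_stop("label volume must be 3-D")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) cp_stop("affine must be 4 x 4")
  structure(list(data = data, affine = affine), class = "label_volume")
}

#' Read a NIfTI-1 label volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_nifti_labels <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    cp_stop("NIfTI header: file shorter than 348 bytes",
            class = "cortiparcel_format_error")
  rd <- function(what, off, n, size, endian) {
    readBin(hdr[(off + 1L):348L], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  sizeof_hdr <- rd("integer", 0L, 1L, 4L, endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd("integer", 0L, 1L, 4L, endian)
    if (sizeof_hdr != 348L)
      cp_stop("NIfTI header: sizeof_hdr is not 348 in either endianness",
              class = "cortiparcel_format_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    cp_stop("NIfTI header: bad magic '%s'", magic,
            class = "cortiparcel_format_error")
  dim0 <- rd("integer", 40L, 8L, 2L, endian)
  if (dim0[1L] < 3L)
    cp_stop("NIfTI header: expected a 3-D image, dim[0] = %d", dim0[1L],
            class = "cortiparcel_format_error")
  dm <- dim0[2:4]
  datatype <- rd("integer", 70L, 1L, 2L, endian)
  pixdim <- rd("double", 76L, 8L, 4L, endian)
  vox_offset <- rd("double", 108L, 1L, 4L, endian)
  sform_code <- rd("integer", 254L, 1L, 2L, endian)
  srow <- matrix(rd("double", 280L, 12L, 4L, endian), 3L, 4L, byrow = TRUE)
  n <- prod(dm)
  # skip to the data (header already consumed 348 bytes)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    `2` = as.integer(readBin(con, "raw", n = n)),                     # uint8
    `4` = readBin(con, "integer", n = n, size = 2L, endian = endian), # int16
    `8` = readBin(con, "integer", n = n, size = 4L, endian = endian), # int32
    `16` = readBin(con, "double", n = n, size = 4L, endian = endian), # float32
    `64` = readBin(con, "double", n = n, size = 8L, endian = endian), # float64
    `512` = readBin(con, "integer", n = n, size = 2L, endian = endian,
                    signed = FALSE),                                  # uint16
    cp_stop("NIfTI: unsupported datatype code %d", datatype,
            class = "cortiparcel_format_error"))
  if (length(vals) < n)
    cp_stop("NIfTI: truncated data section",
            class = "cortiparcel_format_error")
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1))
  else diag(c(pixdim[2:4], 1))
  label_volume(array(as.integer(round(vals)), dm), affine)
}

#' Write a NIfTI-1 label volume (int32, little-endian)
#'
#' @param vol A [label_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @export
write_nifti_labels <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  hdr <- raw(348L)
  put <- function(hdr, bytes, off) {
    hdr[(off + 1L):(off + length(bytes))] <- bytes
    hdr
  }
  wb <- function(x, size, what = "integer")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             raw(), size = size, endian = "little")
  dm <- dim(vol$data)
  hdr <- put(hdr, wb(348L, 4L), 0L)
  hdr <- put(hdr, wb(c(3L, dm, 1L, 1L, 1L, 1L), 2L), 40L)
  hdr <- put(hdr, wb(8L, 2L), 70L)                          # datatype int32
  hdr <- put(hdr, wb(32L, 2L), 72L)                         # bitpix
  hdr <- put(hdr, wb(c(1, 1, 1, 1, 0, 0, 0, 0), 4L, "double"), 76L)
  hdr <- put(hdr, wb(352, 4L, "double"), 108L)              # vox_offset
  hdr <- put(hdr, wb(1L, 2L), 254L)                         # sform_code
  hdr <- put(hdr, wb(as.numeric(t(vol$affine[1:3, ])), 4L, "double"), 280L)
  hdr <- put(hdr, charToRaw("n+1"), 344L)
  writeBin(hdr, con)
  writeBin(raw(4L), con)                                    # extension flag
  writeBin(as.integer(vol$data), con, size = 4L, endian = "little")
  invisible(path)
}
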