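## Surface file I/O: Wavefront OBJ + one-integer-per-line label text, and
## GIfTI (.surf.gii / .label.gii). GIfTI support covers ASCII, Base64Binary
## and GZipBase64Binary encodings of float32/int32/uint8 data arrays, which is
## what FreeSurfer/nibabel emit for surfaces and label maps.

#' Read a labeled surface from files
#'
#' The mesh may be a Wavefront OBJ (`.obj`) or a GIfTI surface
#' (`.gii`/`.surf.gii`); labels may be a plain-text file with one integer per
#' vertex per line, or a GIfTI label array (`.label.gii`, whose label table is
#' used as the region-code table).
#'
#' @param mesh_path Path to the mesh file.
#' @param labels_path Path to the per-vertex labels.
#' @return A [labeled_surface()].
#' @export
read_labeled_surface <- function(mesh_path, labels_path) {
  mesh <- if (grepl("\\.gii$", mesh_path, ignore.case = TRUE))
    read_gifti_surface(mesh_path)
  else
    read_obj(mesh_path)
  if (grepl("\\.gii$", labels_path, ignore.case = TRUE)) {
    lab <- read_gifti_labels(labels_path)
    labels <- lab$labels
    label_table <- lab$label_table
  } else {
    labels <- as.integer(readLines(labels_path, warn = FALSE))
    label_table <- NULL
  }
  if (length(labels) != nrow(mesh$vertices))
    cp_stop("label count (%d) does not match vertex count (%d)",
            length(labels), nrow(mesh$vertices))
  labeled_surface(mesh$vertices, mesh$triangles, labels, label_table)
}

#' Write a labeled surface as OBJ + text labels
#'
#' @param surface A [labeled_surface()].
#' @param mesh_path Output `.obj` path.
#' @param labels_path Output text-label path (one integer per vertex line).
#' @export
write_labeled_surface <- function(surface, mesh_path, labels_path) {
  write_obj(surface$vertices, surface$triangles, mesh_path)
  writeLines(as.character(surface$vertex_labels), labels_path)
  invisible(mesh_path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl))
    cp_stop("OBJ file '%s' has no vertices or no faces", path,
            class = "cortiparcel_format_error")
  verts <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  ftok <- strsplit(trimws(sub("^f ", "", fl)), "\\s+")
  if (any(vapply(ftok, length, 1L) != 3L))
    cp_stop("OBJ file '%s' contains non-triangular faces", path,
            class = "cortiparcel_format_error")
  idx <- vapply(ftok, function(x) as.integer(sub("/.*", "", x)), integer(3L))
  list(vertices = verts, triangles = t(idx))
}

write_obj <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cortiparcel surface", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     vertices[, 1L], vertices[, 2L], vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     triangles[, 1L], triangles[, 2L], triangles[, 3L]), con)
  invisible(path)
}

## ---- GIfTI ----------------------------------------------------------------

gifti_decode_array <- function(da) {
  enc <- xml2::xml_attr(da, "Encoding")
  dt <- xml2::xml_attr(da, "DataType")
  endian <- if (identical(xml2::xml_attr(da, "Endian"), "BigEndian"))
    "big" else "little"
  dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
  dim1 <- xml2::xml_attr(da, "Dim1")
  dim1 <- if (is.na(dim1)) 1L else as.integer(dim1)
  order <- xml2::xml_attr(da, "ArrayIndexingOrder")
  data_node <- xml2::xml_find_first(da, ".//*[local-name()='Data']")
  txt <- xml2::xml_text(data_node)
  vals <- switch(enc,
    ASCII = scan(text = txt, quiet = TRUE),
    Base64Binary = ,
    GZipBase64Binary = {
      bin <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary")
        bin <- memDecompress(bin, type = "gzip")
      switch(dt,
             NIFTI_TYPE_FLOAT32 = readBin(bin, "double", length(bin) %/% 4L,
                                          size = 4L, endian = endian),
             NIFTI_TYPE_FLOAT64 = readBin(bin, "double", length(bin) %/% 8L,
                                          size = 8L, endian = endian),
             NIFTI_TYPE_INT32 = readBin(bin, "integer", length(bin) %/% 4L,
                                        size = 4L, endian = endian),
             NIFTI_TYPE_UINT8 = as.integer(bin),
             cp_stop("GIfTI: unsupported DataType '%s'", dt,
                     class = "cortiparcel_format_error"))
    },
    cp_stop("GIfTI: unsupported Encoding '%s'", enc,
            class = "cortiparcel_format_error"))
  if (length(vals) != dim0 * dim1)
    cp_stop("GIfTI: DataArray length %d does not match Dim0*Dim1 = %d",
            length(vals), dim0 * dim1, class = "cortiparcel_format_error")
  if (dim1 == 1L) return(matrix(vals, ncol = 1L))
  matrix(vals, ncol = dim1, byrow = !identical(order, "ColumnMajorOrder"))
}

gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//*[local-name()='DataArray']")
  if (!length(das))
    cp_stop("GIfTI file '%s' has no DataArray elements", path,
            class = "cortiparcel_format_error")
  list(doc = doc, das = das,
       intents = xml2::xml_attr(das, "Intent"))
}

read_gifti_surface <- function(path) {
  g <- gifti_arrays(path)
  ip <- which(g$intents == "NIFTI_INTENT_POINTSET")
  it <- which(g$intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(ip) || !length(it))
    cp_stop("GIfTI surface '%s': missing POINTSET or TRIANGLE array", path,
            class = "cortiparcel_format_error")
  verts <- gifti_decode_array(g$das[[ip[1L]]])
  tris <- gifti_decode_array(g$das[[it[1L]]]) + 1L   # GIfTI is 0-based
  list(vertices = verts, triangles = tris)
}

read_gifti_labels <- function(path) {
  g <- gifti_arrays(path)
  il <- which(g$intents == "NIFTI_INTENT_LABEL")
  if (!length(il)) il <- 1L
  labels <- as.integer(gifti_decode_array(g$das[[il[1L]]]))
  lab_nodes <- xml2::xml_find_all(g$doc, ".//*[local-name()='Label']")
  label_table <- NULL
  if (length(lab_nodes)) {
    key <- xml2::xml_attr(lab_nodes, "Key")
    key[is.na(key)] <- xml2::xml_attr(lab_nodes, "Index")[is.na(key)]
    label_table <- data.frame(label = as.integer(key),
                              name = xml2::xml_text(lab_nodes),
                              stringsAsFactors = FALSE)
    label_table <- label_table[label_table$label %in% labels, , drop = FALSE]
    if (!nrow(label_table)) label_table <- NULL
  }
  list(labels = labels, label_table = label_table)
}

#' Write a per-vertex label array as a GIfTI label file
#'
#' @param labels Integer vector, one label per vertex (NA allowed; written
#'   as 0).
#' @param label_table Data frame with columns `label` and `name`.
#' @param path Output `.label.gii` path.
#' @export
write_gifti_labels <- function(labels, label_table, path) {
  labels <- as.integer(labels)
  labels[is.na(labels)] <- 0L
  lab_xml <- sprintf('      <Label Key="%d"><![CDATA[%s]]></Label>',
                     label_table$label, label_table$name)
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<GIFTI Version="1.0" NumberOfDataArrays="1">',
           '  <LabelTable>', lab_xml, '  </LabelTable>',
           sprintf(paste0('  <DataArray Intent="NIFTI_INTENT_LABEL" ',
                          'DataType="NIFTI_TYPE_INT32" ',
                          'ArrayIndexingOrder="RowMajorOrder" ',
                          'Dimensionality="1" Dim0="%d" Encoding="ASCII" ',
                          'Endian="LittleEndian" ExternalFileName="" ',
                          'ExternalFileOffset="">'), length(labels)),
           '    <Data>',
           paste(labels, collapse = " "),
           '    </Data>', '  </DataArray>', '</GIFTI>')
  writeLines(xml, path)
  invisible(path)
}
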