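## Fiber-bundle atlases.
##
## A bundle is a named set of 21-point fibers plus the metadata the pipeline
## needs: a maximum classification distance (mm), the 21-point centroid
## (pointwise mean of the fibers), the two anatomical region codes its
## extremities connect, and the hemisphere. Superficial-white-matter bundles
## encode the regions in their name (e.g. "lh_PoC-PrC_0"); deep-white-matter
## bundles (e.g. "AR_LEFT") carry the region pair as explicit metadata.

#' Construct a bundle
#'
#' @param name Bundle name. SWM convention `"<lh|rh>_<A>-<B>_<k>"`, or any
#'   name when `region_start`/`region_end` are given explicitly.
#' @param fibers List of 21 x 3 matrices.
#' @param threshold_mm Maximum corresponding-point distance for a tractogram
#'   fiber to be claimed by this bundle (> 0).
#' @param region_start,region_end Region codes of the bundle extremities; if
#'   `NULL`, parsed from `name`.
#' @param hemisphere `"left"` or `"right"`; if `NULL`, parsed from `name`.
#' @return An object of class `bundle` with a `centroid` field (pointwise mean
#'   of the fibers).
#' @export
bundle <- function(name, fibers, threshold_mm, region_start = NULL,
                   region_end = NULL, hemisphere = NULL) {
  if (!is.list(fibers) || !length(fibers))
    cp_stop("bundle '%s' needs at least one fiber", name)
  fibers <- lapply(fibers, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != 21L || ncol(f) != 3L)
      cp_stop("bundle '%s': every fiber must be a 21 x 3 matrix", name)
    storage.mode(f) <- "double"
    f
  })
  if (!is.numeric(threshold_mm) || threshold_mm <= 0)
    cp_stop("bundle '%s': threshold_mm must be > 0", name)
  if (is.null(region_start) || is.null(region_end) || is.null(hemisphere)) {
    p <- parse_bundle_name(name)
    if (is.null(region_start)) region_start <- p$region_start
    if (is.null(region_end)) region_end <- p$region_end
    if (is.null(hemisphere)) hemisphere <- p$hemisphere
  }
  centroid <- Reduce(`+`, fibers) / length(fibers)
  structure(list(name = name, fibers = fibers,
                 threshold_mm = as.numeric(threshold_mm),
                 centroid = centroid,
                 region_start = region_start, region_end = region_end,
                 hemisphere = hemisphere),
            class = "bundle")
}

#' Construct a bundle atlas
#'
#' @param bundles List of [bundle()] objects with unique names.
#' @return An object of class `bundle_atlas`; bundles are stored sorted by
#'   name so downstream sub-parcel labels are deterministic.
#' @export
bundle_atlas <- function(bundles) {
  if (!length(bundles)) cp_stop("empty bundle atlas")
  nms <- vapply(bundles, function(b) b$name, "")
  if (anyDuplicated(nms)) cp_stop("duplicate bundle names: %s",
                                  paste(nms[duplicated(nms)], collapse = ", "))
  bundles <- bundles[order(nms)]
  names(bundles) <- sort(nms)
  structure(list(bundles = bundles), class = "bundle_atlas")
}

#' @export
print.bundle_atlas <- function(x, ...) {
  nf <- sum(vapply(x$bundles, function(b) length(b$fibers), 1L))
  cat(sprintf("bundle_atlas: %d bundles, %d fibers\n", length(x$bundles), nf))
  invisible(x)
}

#' Parse a bundle name into its anatomical components
#'
#' SWM names follow `"<lh|rh>_<regionA>-<regionB>_<index>"` (intra-region
#' bundles repeat the region, e.g. `"rh_SM-SM_2"`). DWM names such as
#' `"AR_LEFT"` do not encode regions and must be resolved through `metadata`.
#'
#' @param name Bundle name.
#' @param metadata Optional named list: `metadata[[name]]` is a list/vector
#'   with elements `region_start` and `region_end` for names that do not
#'   follow the SWM convention.
#' @return List with `hemisphere` (`"left"`/`"right"`), `region_start`,
#'   `region_end`, `index`.
#' @export
parse_bundle_name <- function(name, metadata = NULL) {
  m <- regexec("^(lh|rh)_([^_-]+)-([^_-]+)_([0-9]+)$", name)
  g <- regmatches(name, m)[[1L]]
  if (length(g) == 5L) {
    return(list(hemisphere = if (g[2L] == "lh") "left" else "right",
                region_start = g[3L], region_end = g[4L],
                index = as.integer(g[5L])))
  }
  md <- regexec("^(.*)_(LEFT|RIGHT)$", name)
  gd <- regmatches(name, md)[[1L]]
  meta <- if (!is.null(metadata)) metadata[[name]] else NULL
  if (length(gd) == 3L && !is.null(meta)) {
    meta <- as.list(meta)
    rs <- meta$region_start %||% meta[[1L]]
    re <- meta$region_end %||% meta[[2L]]
    return(list(hemisphere = if (gd[3L] == "LEFT") "left" else "right",
                region_start = rs, region_end = re, index = 0L))
  }
  cp_stop("cannot parse bundle name '%s' (no SWM pattern, no metadata)", name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a bundle atlas directory
#'
#' On disk an atlas is a directory with one TCK file per bundle
#' (`<name>.tck`) and a `bundles.tsv` metadata table with columns `name`,
#' `threshold_mm`, `region_start`, `region_end`, `hemisphere`.
#'
#' @param dir Atlas directory.
#' @return `read_bundle_atlas()` returns a [bundle_atlas()].
#' @export
read_bundle_atlas <- function(dir) {
  meta_path <- file.path(dir, "bundles.tsv")
  if (!file.exists(meta_path))
    cp_stop("atlas directory '%s' has no bundles.tsv", dir)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  bundles <- lapply(seq_len(nrow(meta)), function(i) {
    t <- read_tractogram(file.path(dir, paste0(meta$name[i], ".tck")))
    bundle(meta$name[i], t$streamlines, meta$threshold_mm[i],
           region_start = meta$region_start[i],
           region_end = meta$region_end[i],
           hemisphere = meta$hemisphere[i])
  })
  bundle_atlas(bundles)
}

#' @rdname read_bundle_atlas
#' @param atlas A [bundle_atlas()].
#' @export
write_bundle_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    name = vapply(atlas$bundles, function(b) b$name, ""),
    threshold_mm = vapply(atlas$bundles, function(b) b$threshold_mm, 1),
    region_start = vapply(atlas$bundles, function(b) b$region_start, ""),
    region_end = vapply(atlas$bundles, function(b) b$region_end, ""),
    hemisphere = vapply(atlas$bundles, function(b) b$hemisphere, ""),
    stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "bundles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (b in atlas$bundles)
    write_tractogram(tractogram(b$fibers, space = "atlas"),
                     file.path(dir, paste0(b$name, ".tck")))
  invisible(dir)
}
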