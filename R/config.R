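#' Pipeline configuration
#'
#' Bundles the three parcellation thresholds and the geometric tolerances used
#' by the intersection stage. All thresholds are fractions in the open unit
#' interval.
#'
#' @param size_thr Minimum preliminary sub-parcel size, as a fraction of the
#'   mean sub-parcel size within the anatomical region (default 0.10).
#' @param dc_thr Minimum per-triangle probability for a triangle to belong to
#'   a sub-parcel's density center (default 0.15).
#' @param idc_thr Minimum normalized density-center overlap (intersection over
#'   the smaller center) for two sub-parcels to become merge candidates
#'   (default 0.10).
#' @param rng_seed Integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed is consumed by the synthetic generator).
#' @param ray_epsilon_mm How far beyond a fiber endpoint the endpoint ray may
#'   hit a triangle and still count, in mm.
#' @param search_radius_mm Radius of the candidate-triangle search around a
#'   fiber endpoint, in mm.
#' @param size_mode `"region_mean"` applies `size_thr` to the region's mean
#'   sub-parcel support size; `"region_fraction"` applies it to the region's
#'   triangle count.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(size_thr = 0.10, dc_thr = 0.15, idc_thr = 0.10,
                            rng_seed = 1L, ray_epsilon_mm = 2,
                            search_radius_mm = 3,
                            size_mode = c("region_mean", "region_fraction")) {
  size_mode <- match.arg(size_mode)
  for (nm in c("size_thr", "dc_thr", "idc_thr")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      cp_stop("%s must be a single number in (0, 1), got %s", nm,
              paste(v, collapse = ","))
  }
  if (ray_epsilon_mm <= 0 || search_radius_mm <= 0)
    cp_stop("geometry tolerances must be positive")
  structure(list(
    size_thr = size_thr, dc_thr = dc_thr, idc_thr = idc_thr,
    rng_seed = as.integer(rng_seed),
    ray_epsilon_mm = ray_epsilon_mm, search_radius_mm = search_radius_mm,
    size_mode = size_mode
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:",
      sprintf("size_thr=%.3g dc_thr=%.3g idc_thr=%.3g", x$size_thr, x$dc_thr,
              x$idc_thr),
      sprintf("(seed %d, ray eps %.3g mm, search radius %.3g mm, %s)",
              x$rng_seed, x$ray_epsilon_mm, x$search_radius_mm, x$size_mode),
      "\n")
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' A flat INI-style `key = value` file; keys match the arguments of
#' [pipeline_config()]. Lines starting with `#` or `;` are comments.
#'
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#;\\[]", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    cp_stop("config line not of the form key = value: %.60s", lines[bad][1L])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  vals <- sub('^"(.*)"$', "\\1", trimws(vals))
  args <- stats::setNames(as.list(vals), keys)
  num <- setdiff(names(args), "size_mode")
  args[num] <- lapply(args[num], as.numeric)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fmt <- function(v) if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 15)
  writeLines(c("# cortiparcel pipeline configuration",
               sprintf("%s = %s", names(cfg), vapply(cfg, fmt, ""))), path)
  invisible(path)
}
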