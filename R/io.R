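# Text-based volume serialization. No NIfTI library is assumed: volumes are
# written as JSON objects carrying dimensions, voxel size, the flattened
# values (column-major) and a free-form metadata block, which plays the role
# of the JSON sidecar that would accompany a NIfTI series.

#' Write a volume (3D/4D array) to JSON
#'
#' @param x Numeric array.
#' @param path Output path.
#' @param voxel_size_mm Optional voxel size.
#' @param meta Optional named list of metadata (sequence, timing, ...).
#' @return `path`, invisibly.
#' @export
write_volume_json <- function(x, path, voxel_size_mm = NULL, meta = list()) {
  obj <- list(dim = dim(x), voxel_size_mm = voxel_size_mm,
              meta = meta, values = as.vector(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a volume written by [write_volume_json()]
#'
#' @param path Input path.
#' @return Array with attributes `voxel_size_mm` and `meta`.
#' @export
read_volume_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- array(as.numeric(obj$values), dim = as.integer(obj$dim))
  attr(x, "voxel_size_mm") <- obj$voxel_size_mm
  attr(x, "meta") <- obj$meta
  x
}

#' Serialize an ASL dataset to a directory of JSON files
#'
#' Writes `control.json`, `label.json` and `series.json` (the sidecar with
#' sequence, per-volume TI/PLD, bolus durations, TE, TR, slice time, alpha,
#' presaturation efficiency and background-suppression settings).
#'
#' @param ds `asl_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_asl_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "asl_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume_json(ds$control, file.path(dir, "control.json"))
  write_volume_json(ds$label, file.path(dir, "label.json"))
  jsonlite::write_json(ds$meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an ASL dataset written by [write_asl_dataset()]
#'
#' @param dir Directory containing the three JSON files.
#' @return `asl_dataset`.
#' @export
read_asl_dataset <- function(dir) {
  control <- read_volume_json(file.path(dir, "control.json"))
  label <- read_volume_json(file.path(dir, "label.json"))
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  attributes(control) <- list(dim = dim(control))
  attributes(label) <- list(dim = dim(label))
  structure(list(control = control, label = label, meta = as.list(meta)),
            class = "asl_dataset")
}

#' Serialize an M0 map with its provenance
#'
#' @param m0 `m0_map`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_m0_map <- function(m0, path) {
  stopifnot(inherits(m0, "m0_map"))
  obj <- list(kind = m0$kind, method = m0$method, options = m0$options,
              dim = if (length(m0$values) > 1) dim(m0$values) else NULL,
              values = as.vector(m0$values))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an M0 map written by [write_m0_map()]
#'
#' @param path Input JSON path.
#' @return `m0_map` with identical values and provenance.
#' @export
read_m0_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- as.numeric(obj$values)
  if (!is.null(obj$dim) && length(obj$dim))
    vals <- array(vals, dim = as.integer(obj$dim))
  new_m0_map(vals, kind = obj$kind, method = obj$method,
             options = as.list(obj$options))
}
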