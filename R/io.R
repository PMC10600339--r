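#' Read and write 3D volumes as NIfTI
#'
#' Volumes are plain 3D R arrays in (x, y, z) index order with voxel-centre
#' world mapping `world = index * spacing` (0-based index), the convention
#' shared by every module of the package. Label volumes are written as unsigned
#' 8-bit integers, intensity volumes as 64-bit floats, so write/read round
#' trips reproduce the array exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid 3D array.
#' @param spacing voxel spacing in mm, 3 positive reals.
#' @param labels logical; write as unsigned 8-bit label volume.
#' @return `read_volume()` returns a list with `grid` (3D array) and `header`
#'   (list with `shape`, `spacing`, `origin`); `write_volume()` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stopf("expected a 3D volume, got %dD", length(d))
  spacing <- attr(img, "pixdim")[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("invalid voxel spacing in NIfTI header")
  grid <- array(as.vector(img), dim = d)
  if (isTRUE(RNifti::niftiHeader(img)$datatype %in% c(2L, 4L, 8L, 256L, 512L)))
    storage.mode(grid) <- "integer"
  hdr <- list(shape = d, spacing = as.double(spacing), origin = c(0, 0, 0))
  list(grid = grid, header = hdr)
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, spacing, path, labels = FALSE) {
  if (length(dim(grid)) != 3) stopf("'grid' must be a 3D array")
  assert_len3(spacing, "spacing")
  if (labels) {
    if (any(grid < 0) || any(grid > 255)) stopf("label values must be in [0, 255]")
    storage.mode(grid) <- "integer"
    dt <- "uint8"
  } else {
    storage.mode(grid) <- "double"
    dt <- "double"
  }
  attr(grid, "pixdim") <- as.double(spacing)
  img <- RNifti::asNifti(grid, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file, rejects unknown keys, and injects defaults for anything
#' omitted. `schema` is a named list of defaults; nested lists validate
#' recursively. An empty file yields the full default tree.
#'
#' @param path YAML file path.
#' @param schema named list of defaults defining the allowed keys.
#' @return the fully resolved configuration list.
#' @export
load_config <- function(path, schema) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  merge_config(cfg, schema, "")
}

merge_config <- function(cfg, schema, prefix) {
  if (!is.list(cfg)) stopf("config section '%s' must be a mapping", prefix)
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s",
          paste0(prefix, unknown, collapse = ", "))
  out <- schema
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      out[[k]] <- merge_config(cfg[[k]], schema[[k]], paste0(prefix, k, "."))
    } else {
      out[[k]] <- cfg[[k]]
    }
  }
  out
}

# append one JSON record to a JSON-lines log
log_jsonl <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}
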