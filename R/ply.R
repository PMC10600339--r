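#' Read and write triangle meshes as PLY
#'
#' Binary little-endian (default) or ascii PLY. Vertex positions are stored as
#' double precision so a write/read round trip is bit-exact; the per-vertex
#' `component_id` and `vertex_uid` tags are preserved as integer vertex
#' properties of the same names.
#'
#' @param mesh a [trimesh()].
#' @param path file path.
#' @param format `"binary"` (binary_little_endian) or `"ascii"`.
#' @return `write_ply()` returns `path` invisibly; `read_ply()` a [trimesh()].
#' @export
write_ply <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  n <- n_vertices(mesh)
  f <- n_faces(mesh)
  header <- c(
    "ply",
    if (format == "binary") "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment flowmesh mesh",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    "property int component_id", "property int vertex_uid",
    sprintf("element face %d", f),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    vlines <- sprintf("%.17g %.17g %.17g %d %d",
                      mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                      mesh$component_id, mesh$vertex_uid)
    writeLines(vlines, con, sep = "\n")
    if (f > 0) {
      flines <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                        mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
      writeLines(flines, con, sep = "\n")
    }
  } else {
    for (i in seq_len(n)) {
      writeBin(as.double(mesh$vertices[i, ]), con, size = 8, endian = "little")
      writeBin(as.integer(c(mesh$component_id[i], mesh$vertex_uid[i])), con,
               size = 4, endian = "little")
    }
    for (i in seq_len(f)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stopf("unexpected end of PLY header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- header[grepl("^format ", header)]
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "", header[grepl("^element vertex ", header)]))
  nf <- as.integer(sub("element face ", "", header[grepl("^element face ", header)]))
  # vertex property schema, in order
  vstart <- which(grepl("^element vertex ", header))
  fstart <- which(grepl("^element face ", header))
  vprops <- header[(vstart + 1):(fstart - 1)]
  vprops <- vprops[grepl("^property ", vprops)]
  ptypes <- vapply(strsplit(vprops, " "), `[`, "", 2)
  pnames <- vapply(strsplit(vprops, " "), `[`, "", 3)
  type_size <- c(char = 1, uchar = 1, short = 2, ushort = 2, int = 4, uint = 4,
                 int32 = 4, float = 4, float32 = 4, double = 8, float64 = 8)
  if (binary) {
    vals <- matrix(0, nv, length(pnames))
    for (i in seq_len(nv)) {
      for (j in seq_along(pnames)) {
        tp <- ptypes[j]
        sz <- type_size[[tp]]
        what <- if (tp %in% c("float", "float32", "double", "float64")) "double" else "integer"
        vals[i, j] <- readBin(con, what, n = 1, size = sz, endian = "little")
      }
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "integer", n = 1, size = 1, signed = FALSE))
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3) stopf("only triangle faces are supported")
      faces[i, ] <- idx + 1L
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(body)]
    vtok <- strsplit(body[seq_len(nv)], "\\s+")
    vals <- t(vapply(vtok, function(t) as.double(t[seq_along(pnames)]),
                     double(length(pnames))))
    ftok <- strsplit(body[nv + seq_len(nf)], "\\s+")
    faces <- t(vapply(ftok, function(t) as.integer(t[2:4]) + 1L, integer(3)))
  }
  colnames(vals) <- pnames
  verts <- vals[, c("x", "y", "z"), drop = FALSE]
  dimnames(verts) <- NULL
  comp <- if ("component_id" %in% pnames) as.integer(vals[, "component_id"]) else NULL
  uid <- if ("vertex_uid" %in% pnames) as.integer(vals[, "vertex_uid"]) else NULL
  trimesh(verts, faces, component_id = comp, vertex_uid = uid)
}
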