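#' Read and write PLY surface meshes
#'
#' Polygon File Format I/O for [surface_mesh()] objects, supporting the
#' `ascii 1.0` and `binary_little_endian 1.0` dialects. Vertex positions are
#' stored as `float` (32-bit), faces as a uchar count followed by int
#' indices; only triangular faces are accepted. A round trip preserves the
#' triangle list exactly and vertex coordinates to float32 precision.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path ending in `.ply`.
#' @param format `"ascii"` or `"binary"` (binary little-endian).
#' @return `read_mesh()` returns a [surface_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  v <- mesh$vertices
  tr <- mesh$triangles
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           if (format == "ascii") "format ascii 1.0"
           else "format binary_little_endian 1.0",
           "comment produced by glomorph; coordinates in micrometres",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(tr)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  if (format == "ascii") {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con, sep = "\n")
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L),
               con, sep = "\n")
  } else {
    writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
    if (nrow(tr) > 0) {
      # interleave the uchar face-size byte with three little-endian ints
      face_block <- vapply(seq_len(nrow(tr)), function(i) {
        c(as.raw(3L), writeBin(as.integer(tr[i, ] - 1L), raw(),
                               size = 4, endian = "little"))
      }, raw(13))
      writeBin(as.vector(face_block), con)
    }
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- read_line_bin(con)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 100) abort("malformed PLY: no end_header found.")
  }
  if (!identical(hdr[1], "ply")) abort("malformed PLY header at line 1: not a PLY file.")
  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt_line)) abort("malformed PLY header: missing 'format' line.")
  fmt <- strsplit(fmt_line[1], " ")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    abort(sprintf("unsupported PLY format '%s'.", fmt))
  nv <- ply_count(hdr, "vertex")
  nf <- ply_count(hdr, "face")
  vprops <- ply_vertex_props(hdr)
  if (!all(c("x", "y", "z") %in% vprops$name))
    abort("PLY vertex element must carry x, y, z properties.")
  if (fmt == "ascii") {
    lines <- readLines(con)
    vl <- lines[seq_len(nv)]
    vm <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), as.numeric))
    fl <- lines[nv + seq_len(nf)]
    fm <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), as.integer))
    if (nf > 0 && any(fm[, 1] != 3L)) abort("non-triangular PLY faces are not supported.")
    v <- vm[, match(c("x", "y", "z"), vprops$name), drop = FALSE]
    tr <- if (nf > 0) fm[, 2:4, drop = FALSE] + 1L else matrix(integer(), 0, 3)
  } else {
    if (any(vprops$size != 4))
      abort("only 4-byte vertex properties are supported in binary PLY.")
    raw_v <- readBin(con, "numeric", n = nv * nrow(vprops), size = 4,
                     endian = "little")
    vm <- matrix(raw_v, ncol = nrow(vprops), byrow = TRUE)
    v <- vm[, match(c("x", "y", "z"), vprops$name), drop = FALSE]
    tr <- matrix(integer(), 0, 3)
    if (nf > 0) {
      tr <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        k <- as.integer(readBin(con, "raw", n = 1))
        if (k != 3L) abort("non-triangular PLY faces are not supported.")
        tr[i, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little") + 1L
      }
    }
  }
  surface_mesh(v, tr)
}

read_line_bin <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) abort("malformed PLY: unexpected end of file in header.")
    if (b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

ply_count <- function(hdr, element) {
  line <- grep(sprintf("^element %s ", element), hdr, value = TRUE)
  if (!length(line)) abort(sprintf("malformed PLY header: no 'element %s' line.", element))
  as.integer(strsplit(line[1], " ")[[1]][3])
}

ply_vertex_props <- function(hdr) {
  vstart <- grep("^element vertex ", hdr)
  rest <- hdr[(vstart + 1):length(hdr)]
  stop_at <- grep("^(element|end_header)", rest)[1]
  props <- grep("^property ", rest[seq_len(stop_at - 1)], value = TRUE)
  parts <- strsplit(props, " ")
  sizes <- c(float = 4L, float32 = 4L, int = 4L, int32 = 4L, uint = 4L,
             double = 8L, uchar = 1L, uint8 = 1L, char = 1L, short = 2L,
             ushort = 2L)
  data.frame(type = vapply(parts, `[`, "", 2),
             name = vapply(parts, `[`, "", 3),
             size = unname(sizes[vapply(parts, `[`, "", 2)]))
}
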