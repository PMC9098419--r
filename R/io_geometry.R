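# Point-cloud and mesh artifacts: whitespace XYZ and PLY (binary
# little-endian by default, ASCII also read/written).

#' Write / read XYZ point clouds
#'
#' Whitespace-delimited `x y z` rows in mm.
#'
#' @param points numeric matrix with 3 columns (mm).
#' @param path file path.
#' @return `write_xyz`: `path` invisibly; `read_xyz`: an N x 3 matrix.
#' @export
write_xyz <- function(points, path) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  utils::write.table(format(points, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  stopifnot(ncol(m) == 3L)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Write a mesh or point cloud as PLY
#'
#' @param x a `surface_mesh`, or an N x 3 matrix of points (cloud only).
#' @param path output path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path, binary = TRUE) {
  if (inherits(x, "surface_mesh")) {
    verts <- x$vertices
    faces <- x$faces
  } else {
    verts <- as.matrix(x)
    stopifnot(ncol(verts) == 3L)
    faces <- matrix(integer(0), 0, 3)
  }
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", nrow(verts)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(faces)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.numeric(t(verts)), con, size = 4, endian = "little")
    if (nrow(faces) > 0) {
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(faces[i, ] - 1L), con, size = 4,
                 endian = "little")
      }
    }
  } else {
    writeLines(apply(verts, 1, function(v)
      paste(format(v, digits = 9), collapse = " ")), con)
    if (nrow(faces) > 0)
      writeLines(apply(faces, 1, function(f)
        paste(c(3L, f - 1L), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PLY mesh or point cloud
#'
#' Supports the subset written by [write_ply] (float32 xyz vertices,
#' uchar-counted int32 triangular faces; ASCII or binary little-endian).
#'
#' @param path file path.
#' @return A list with `vertices` (N x 3) and `faces` (F x 3, 1-based;
#'   zero rows for a bare cloud).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 100) stop("malformed PLY header", call. = FALSE)
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", hdr,
                                                  value = TRUE))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("^element face ", "", nf_line))
        else 0L
  if (fmt == "binary_little_endian") {
    verts <- matrix(readBin(con, numeric(), n = 3L * nv, size = 4,
                            endian = "little"), ncol = 3, byrow = TRUE)
    faces <- matrix(integer(0), 0, 3)
    if (nf > 0) {
      faces <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        cnt <- as.integer(readBin(con, raw(), n = 1L))
        if (cnt != 3L) stop("only triangular faces supported", call. = FALSE)
        faces[i, ] <- readBin(con, integer(), n = 3L, size = 4,
                              endian = "little") + 1L
      }
    }
  } else {
    txt <- readLines(con)
    vrows <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    verts <- matrix(as.numeric(unlist(vrows)), ncol = 3, byrow = TRUE)
    faces <- matrix(integer(0), 0, 3)
    if (nf > 0) {
      frows <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
      fm <- matrix(as.integer(unlist(frows)), ncol = 4, byrow = TRUE)
      if (any(fm[, 1] != 3L))
        stop("only triangular faces supported", call. = FALSE)
      faces <- fm[, 2:4, drop = FALSE] + 1L
    }
  }
  dimnames(verts) <- list(NULL, c("x", "y", "z"))
  list(vertices = verts, faces = faces)
}
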