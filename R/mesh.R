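# Minimal triangle-mesh container plus STL reading/writing. STL carries no
# units; every mesh in this package is in millimetres and the scene archive
# records that explicitly. No mesh library for R ships with this stack, so
# the (small) format support lives here.

#' Triangle mesh
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices,
#'   counter-clockwise when viewed from outside.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices)); storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces)); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || any(!is.finite(vertices))) {
    om_error("config_error", "vertices must be a finite n x 3 matrix")
  }
  if (ncol(faces) != 3L || any(faces < 1L) || any(faces > nrow(vertices))) {
    om_error("config_error", "faces must be m x 3 indices into the vertex table")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3L], , drop = FALSE])
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedra; positive for a closed,
#' outward-oriented surface. Meaningless for open meshes.
#'
#' @param mesh `tri_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cbind(fc$b[, 2] * fc$c[, 3] - fc$b[, 3] * fc$c[, 2],
              fc$b[, 3] * fc$c[, 1] - fc$b[, 1] * fc$c[, 3],
              fc$b[, 1] * fc$c[, 2] - fc$b[, 2] * fc$c[, 1])
  sum(rowSums(fc$a * cr)) / 6
}

#' Check that every edge is shared by exactly two faces
#'
#' @param mesh `tri_mesh`.
#' @return `TRUE` if the surface is closed (watertight in the edge-manifold
#'   sense), else `FALSE`.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  u <- fc$b - fc$a; v <- fc$c - fc$a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Read an STL file
#'
#' Autodetects binary vs ASCII. Triangles are read as a vertex soup and
#' identical coordinates are merged, so shared edges become shared
#' vertices. Units are taken to be millimetres.
#'
#' @param path file path.
#' @return `tri_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) format_error(sprintf("STL file not found: %s", path))
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = 84L)
  close(con)
  if (length(head_raw) < 15L) format_error(sprintf("file too short for STL: %s", path))
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") &&
    is_ascii_stl(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, head_raw)
  soup_to_mesh(tri)
}

# "solid" headers also occur in binary files; confirm by looking for "facet"
is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 10L, warn = FALSE))
  any(grepl("facet", txt, fixed = TRUE)) || length(txt) <= 1L
}

read_stl_binary <- function(path, head_raw) {
  sz <- file.info(path)$size
  if (sz < 84) format_error("binary STL truncated before triangle count")
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (n < 0 || sz < 84 + 50 * as.numeric(n)) {
    format_error(sprintf("binary STL corrupt: declares %d triangles for %d bytes", n, sz))
  }
  raw <- readBin(con, "raw", n = 50L * n)
  m <- matrix(raw, nrow = 50L)
  # 12 floats (normal + 3 vertices) + 2-byte attribute per record
  floats <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric",
                    n = 12L * n, size = 4L, endian = "little")
  fm <- matrix(floats, ncol = 12L, byrow = TRUE)
  # interleave corners so rows run v1,v2,v3 per triangle
  out <- matrix(0, nrow = 3L * n, ncol = 3L)
  out[seq(1L, 3L * n, by = 3L), ] <- fm[, 4:6, drop = FALSE]
  out[seq(2L, 3L * n, by = 3L), ] <- fm[, 7:9, drop = FALSE]
  out[seq(3L, 3L * n, by = 3L), ] <- fm[, 10:12, drop = FALSE]
  out
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    format_error(sprintf("ASCII STL malformed: %d vertex lines", length(vl)))
  }
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(v))) format_error("ASCII STL: non-numeric vertex line")
    v
  }, numeric(3)))
  nums
}

soup_to_mesh <- function(tri) {
  n <- nrow(tri) / 3L
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Write an STL file
#'
#' @param mesh `tri_mesh` (mm).
#' @param path output path.
#' @param ascii write the ASCII dialect instead of binary (default binary,
#'   little-endian).
#' @param name solid name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE, name = "orthomount") {
  stopifnot(inherits(mesh, "tri_mesh"))
  fc <- face_corners(mesh)
  nrm <- face_normals(mesh)
  n <- nrow(mesh$faces)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    block <- sprintf(
      "  facet normal %.9g %.9g %.9g\n    outer loop\n      vertex %.9g %.9g %.9g\n      vertex %.9g %.9g %.9g\n      vertex %.9g %.9g %.9g\n    endloop\n  endfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      fc$a[, 1], fc$a[, 2], fc$a[, 3],
      fc$b[, 1], fc$b[, 2], fc$b[, 3],
      fc$c[, 1], fc$c[, 2], fc$c[, 3])
    writeLines(block, con)
    writeLines(sprintf("endsolid %s", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", substr(paste0("orthomount mm ", name), 1, 80)))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    rec <- cbind(nrm, fc$a, fc$b, fc$c)  # n x 12 floats
    flat <- as.numeric(t(rec))
    fbytes <- writeBin(flat, raw(), size = 4L, endian = "little")
    fmat <- matrix(fbytes, nrow = 48L)
    out <- rbind(fmat, matrix(as.raw(0), nrow = 2L, ncol = n))
    writeBin(as.vector(out), con)
  }
  invisible(path)
}
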