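#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` matrix of
#' vertex coordinates in millimetres and an `m x 3` integer matrix of
#' 1-based vertex indices per triangular face.  Faces are oriented
#' counter-clockwise seen from outside (outward normals).
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates (mm).
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Enclosed volume of a closed oriented mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra
#' against the origin); exact for watertight, consistently oriented meshes.
#'
#' @param mesh a `surface_mesh`.
#' @return Volume in mm^3 (positive for outward-oriented meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @param faces optional subset of face indices.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Watertightness check
#'
#' A closed, consistently oriented 2-manifold has every undirected edge
#' shared by exactly two faces, traversed once in each direction.
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE` if watertight and consistently oriented.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])   # directed half-edges
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' Apply a rigid motion to a mesh
#' @param mesh a `surface_mesh`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric offset (mm).
#' @return Transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  surface_mesh(v, mesh$faces)
}

#' Write a mesh as STL
#'
#' Both the binary and ASCII stereolithography dialects are supported.
#' Binary STL stores coordinates in single precision; a round trip through
#' either dialect preserves vertices to single precision.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param binary write the binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  nf <- nrow(f)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 floats + attribute count per facet
    dat <- t(cbind(n, a, b, c_))            # 12 x nf, column = facet
    for (i in seq_len(nf)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid vafamorph", con)
    fmt <- paste0(
      "facet normal %.9g %.9g %.9g\n outer loop\n",
      "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
      "  vertex %.9g %.9g %.9g\n endloop\nendfacet")
    lines <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                     a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                     c_[, 1], c_[, 2], c_[, 3])
    writeLines(lines, con)
    writeLines("endsolid vafamorph", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII, auto-detected)
#'
#' Duplicate vertices are merged so that the result is suitable for
#' watertightness checks and voxelization.
#'
#' @param path STL file path.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 6L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    is_probably_ascii_stl(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_triangle_soup(tri)
}

is_probably_ascii_stl <- function(path) {
  # binary files may also begin with "solid": verify the facet count matches
  sz <- file.info(path)$size
  if (sz < 84) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  seek(con, 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  sz != 84 + 50 * as.numeric(nf)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", n = 50 * nf)
  dim(raw) <- c(50, nf)
  vals <- readBin(as.vector(raw[1:48, ]), "numeric", n = 12 * nf, size = 4,
                  endian = "little")
  m <- matrix(vals, nrow = 12)          # rows: normal(3), v1(3), v2(3), v3(3)
  t(m[4:12, , drop = FALSE])            # nf x 9
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  parts <- strsplit(trimws(vl), "\\s+")
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(xyz) %% 3 != 0) stop("malformed ASCII STL: vertex count not 3 per facet")
  nf <- nrow(xyz) / 3
  cbind(xyz[seq(1, by = 3, length.out = nf), , drop = FALSE],
        xyz[seq(2, by = 3, length.out = nf), , drop = FALSE],
        xyz[seq(3, by = 3, length.out = nf), , drop = FALSE])
}

weld_triangle_soup <- function(tri) {
  nf <- nrow(tri)
  verts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, unique(key))
  vu <- verts[!duplicated(key), , drop = FALSE]
  faces <- cbind(uid[seq_len(nf)], uid[nf + seq_len(nf)], uid[2 * nf + seq_len(nf)])
  surface_mesh(vu, faces)
}
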