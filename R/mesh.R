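#' Triangle surface meshes
#'
#' A minimal triangle-mesh container: `vertices` (n x 3, mm), `faces`
#' (m x 3, 1-based vertex indices), and per-vertex unit `normals`. For the
#' synthetic closed cavities generated by this package the faces are wound
#' so normals point into the lumen (the endoscope views the interior).
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals Optional n x 3 matrix of unit vertex normals; computed
#'   area-weighted from the faces when omitted.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- rbind3(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(nrow(faces) >= 1, all(faces >= 1), all(faces <= nrow(vertices)))
  mesh <- structure(
    list(vertices = vertices, faces = faces, normals = NULL),
    class = "tri_mesh"
  )
  mesh$normals <- if (is.null(normals)) vertex_normals(mesh) else rbind3(normals)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Area-weighted vertex normals
#'
#' Averages the (area-weighted) normals of the faces incident to each
#' vertex and normalizes. Orientation follows the face winding: meshes
#' wound counter-clockwise when seen from the interior get inward normals.
#' Isolated vertices get a zero normal and a warning.
#'
#' @param mesh A `tri_mesh` (the `normals` field is ignored).
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F_ <- mesh$faces
  e1 <- V[F_[, 2], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  e2 <- V[F_[, 3], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )  # cross product length = 2 * area, so summing is area weighting
  N <- matrix(0, nrow(V), 3)
  for (c_ in 1:3) {
    for (k in 1:3) {
      N[, c_] <- N[, c_] + tabulate2(F_[, k], fn[, c_], nrow(V))
    }
  }
  len <- sqrt(rowSums(N^2))
  iso <- len < 1e-12
  if (any(iso)) {
    warning(sum(iso), " isolated or degenerate vertices have zero normals")
    len[iso] <- 1
  }
  N / len
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Topological checks for closed meshes
#'
#' `mesh_is_watertight()` checks every edge is shared by exactly two faces;
#' `mesh_euler_characteristic()` returns V - E + F (2 for a genus-0 closed
#' surface).
#'
#' @param mesh A `tri_mesh`.
#' @export
mesh_is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  all(table(paste(e[, 1], e[, 2])) == 2)
}

#' @rdname mesh_is_watertight
#' @export
mesh_euler_characteristic <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

mesh_edges <- function(mesh) {
  F_ <- mesh$faces
  e <- rbind(F_[, c(1, 2)], F_[, c(2, 3)], F_[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# Cached C++ acceleration structure, built lazily per mesh object.
mesh_accel <- function(mesh) {
  acc <- attr(mesh, "accel", exact = TRUE)
  if (is.null(acc)) acc <- accel_build_cpp(mesh$vertices, mesh$faces)
  acc
}

#' Precompute the ray-casting acceleration structure
#'
#' Optional: every ray-based operation builds (and caches on the returned
#' object) a uniform-grid structure automatically; call this once when the
#' same mesh is queried many times.
#'
#' @param mesh A `tri_mesh`.
#' @return The mesh with the structure attached.
#' @export
mesh_prepare <- function(mesh) {
  attr(mesh, "accel") <- accel_build_cpp(mesh$vertices, mesh$faces)
  mesh
}

#' Mesh file I/O (ASCII PLY, OBJ, STL)
#'
#' Format is chosen from the file extension. PLY files are written as
#' ASCII with `x y z nx ny nz` vertex properties; STL reading re-indexes
#' duplicated vertices.
#'
#' @param path File path ending in `.ply`, `.obj` or `.stl`.
#' @param mesh A `tri_mesh`.
#' @return `read_mesh()` returns a `tri_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stop("unsupported mesh format: .", ext)
  )
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  writeLines(c(
    "ply", "format ascii 1.0", "comment units mm",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    paste("element face", m),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  vd <- cbind(mesh$vertices, mesh$normals)
  writeLines(apply(format(vd, trim = TRUE, digits = 9, scientific = FALSE), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1, mesh$faces[, 3] - 1), con)
}

read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vl <- lines[(end + 1):(end + nv)]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), nrow = nv, byrow = TRUE)
  fl <- lines[(end + nv + 1):(end + nv + nf)]
  fdat <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))), nrow = nf, byrow = TRUE)
  stopifnot(all(fdat[, 1] == 3))
  normals <- if (ncol(vdat) >= 6) vdat[, 4:6, drop = FALSE] else NULL
  tri_mesh(vdat[, 1:3, drop = FALSE], fdat[, 2:4, drop = FALSE] + 1L, normals)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(paste("vn", mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  parse_nums <- function(x, prefix) {
    toks <- strsplit(trimws(sub(prefix, "", x)), "\\s+")
    matrix(as.numeric(unlist(toks)), nrow = length(x), byrow = TRUE)
  }
  V <- parse_nums(vl, "^v")
  Fidx <- t(vapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(tok) {
    as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1))
  }, integer(3)))
  tri_mesh(V, Fidx)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lumenreg", con)
  V <- mesh$vertices; F_ <- mesh$faces
  for (f in seq_len(nrow(F_))) {
    a <- V[F_[f, 1], ]; b <- V[F_[f, 2], ]; c_ <- V[F_[f, 3], ]
    n <- cross3(b - a, c_ - a)
    n <- n / max(sqrt(sum(n^2)), 1e-12)
    writeLines(c(
      paste("facet normal", n[1], n[2], n[3]),
      "  outer loop",
      paste("    vertex", a[1], a[2], a[3]),
      paste("    vertex", b[1], b[2], b[3]),
      paste("    vertex", c_[1], c_[2], c_[3]),
      "  endloop", "endfacet"
    ), con)
  }
  writeLines("endsolid lumenreg", con)
}

read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("vertex", lines, value = TRUE)
  coords <- matrix(as.numeric(unlist(strsplit(trimws(sub(".*vertex", "", vl)), "\\s+"))),
                   ncol = 3, byrow = TRUE)
  key <- apply(round(coords, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  V <- coords[!duplicated(key), , drop = FALSE]
  F_ <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(V, F_)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
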