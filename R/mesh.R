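#' Triangle mesh objects
#'
#' A `triangle_mesh` is a closed, oriented triangulated surface in world (mm)
#' coordinates: an `n x 3` matrix of vertex positions and an `m x 3` integer
#' matrix of vertex indices per face, wound counter-clockwise when seen from
#' outside so that face normals point away from the enclosed solid. Vertex
#' normals (the Gauss-map image of each vertex on the unit sphere) are attached
#' lazily by [compute_vertex_normals()].
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param normals optional numeric matrix of unit vertex normals.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  chi <- tryCatch(euler_characteristic(x), error = function(e) NA)
  cat(sprintf("  watertight: %s, Euler characteristic: %s\n",
              is_watertight(x), format(chi)))
  cat(sprintf("  enclosed volume: %.2f mm^3, area: %.2f mm^2\n",
              mesh_volume(x), sum(face_areas(x))))
  invisible(x)
}

# undirected edges, one row per unique edge
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- pmin(e[, 1L], e[, 2L]) + pmax(e[, 1L], e[, 2L]) * (nrow(mesh$vertices) + 1)
  e[!duplicated(key), , drop = FALSE]
}

#' Euler characteristic V - E + F of a mesh
#'
#' For a closed connected surface of genus g this equals `2 - 2g`:
#' 2 for a topological sphere, 0 for a torus.
#' @param mesh a [triangle_mesh()].
#' @return integer scalar.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Check that every edge is shared by exactly two faces
#'
#' @param mesh a [triangle_mesh()].
#' @return logical; `TRUE` for a closed edge-manifold surface.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  n <- nrow(mesh$vertices) + 1
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- pmin(e[, 1L], e[, 2L]) + pmax(e[, 1L], e[, 2L]) * n
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  # coherent orientation: each directed edge appears exactly once
  dkey <- e[, 1L] + e[, 2L] * n
  !anyDuplicated(dkey)
}

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Per-face areas (mm^2)
#' @param mesh a [triangle_mesh()].
#' @return numeric vector, one area per face.
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  nrm <- sqrt(rowSums(cr * cr))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' Enclosed volume of a closed oriented mesh (divergence theorem)
#'
#' Sums signed tetrahedron volumes against the origin; positive for outward
#' orientation.
#' @param mesh a [triangle_mesh()].
#' @param signed if `FALSE` (default) the absolute value is returned.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  vol <- sum(det6) / 6
  if (signed) vol else abs(vol)
}

#' Area-weighted outward vertex normals
#'
#' Each vertex normal is the sum of incident face normals weighted by face
#' area, normalised to unit length. This is the discrete Gauss map n(p).
#'
#' @param mesh a [triangle_mesh()].
#' @return the mesh with a `normals` matrix attached.
#' @export
compute_vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # area-weighted face normals (length = 2*area)
  f <- mesh$faces
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(cr[, k], f[, j])
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc[, 1L]
    }
  }
  len <- sqrt(rowSums(n * n))
  bad <- which(len == 0)
  if (length(bad) > 0)
    stop(sprintf("degenerate normal: vertex %d has zero-area incident faces only",
                 bad[1L]))
  mesh$normals <- n / len
  mesh
}

# sparse vertex adjacency (symmetric logical pattern)
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(nv, nv))
}

# connected components of the vertex graph; returns integer labels per vertex
mesh_components <- function(mesh) {
  adj <- mesh_adjacency(mesh)
  nv <- nrow(mesh$vertices)
  comp <- integer(nv)
  cur <- 0L
  adj_l <- as(adj, "CsparseMatrix")
  p <- adj_l@p; ii <- adj_l@i
  for (s in seq_len(nv)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- unlist(lapply(frontier, function(v) ii[seq.int(p[v] + 1L, length.out = p[v + 1L] - p[v])] + 1L))
      nb <- unique(nb[comp[nb] == 0L])
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 matrix applied to vertex coordinates.
#' @param translation length-3 offset added after rotation.
#' @return transformed mesh (normals dropped; recompute if needed).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2L, translation, "+")
  triangle_mesh(v, mesh$faces)
}

#' Write a mesh to an ASCII PLY file
#'
#' Optional per-vertex scalar columns (e.g. curvature values) are stored as
#' extra float properties for inspection in external viewers.
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param scalars optional named list of per-vertex numeric vectors.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z"), con)
  vdat <- mesh$vertices
  if (!is.null(scalars)) {
    for (nm in names(scalars)) {
      writeLines(sprintf("property float %s", nm), con)
      vdat <- cbind(vdat, scalars[[nm]])
    }
  }
  writeLines(c(sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(vdat, trim = TRUE, digits = 9), 1L, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file written by [write_ply()]
#' @param path input file path.
#' @return a [triangle_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vl <- lines[(hdr_end + 1L):(hdr_end + nv)]
  v <- do.call(rbind, lapply(strsplit(vl, " "), function(x) as.numeric(x[1:3])))
  fl <- lines[(hdr_end + nv + 1L):(hdr_end + nv + nf)]
  f <- do.call(rbind, lapply(strsplit(fl, " "), function(x) as.integer(x[2:4]) + 1L))
  triangle_mesh(v, f)
}

#' Write a mesh to a Wavefront OBJ file
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
  invisible(path)
}
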