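#' Analytic test surfaces
#'
#' Parametric meshes with known curvature, used to validate the curvature
#' estimator: a subdivided icosahedron projected onto a sphere (uniform,
#' pole-free sampling), a capped cylinder, a torus and a flat plane patch.
#'
#' @param radius sphere/cylinder radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions of the icosahedron.
#' @param center sphere centre.
#' @return a [triangle_mesh()] with outward orientation.
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e[, 1], e[, 2]) + pmax(e[, 1], e[, 2]) * (nv + 1)
    ukey <- unique(key)
    mid_id <- nv + match(key, ukey)
    first <- !duplicated(key)
    mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids * mids))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- v * radius
  v <- sweep(v, 2L, center, "+")
  triangle_mesh(v, f)
}

#' @rdname mesh_icosphere
#' @param height cylinder height (mm), axis along z, centred at the origin.
#' @param n_theta,n_z angular and axial sampling counts.
#' @export
mesh_cylinder <- function(radius = 1, height = 4, n_theta = 64, n_z = 32) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  z <- seq(-height / 2, height / 2, length.out = n_z)
  v <- cbind(radius * cos(rep(theta, times = n_z)),
             radius * sin(rep(theta, times = n_z)),
             rep(z, each = n_theta))
  idx <- function(i, k) (k - 1L) * n_theta + i  # i: angle, k: level
  i <- rep(seq_len(n_theta), times = n_z - 1L)
  k <- rep(seq_len(n_z - 1L), each = n_theta)
  ip <- i %% n_theta + 1L
  # outward winding for CCW-from-outside quads on the lateral wall
  f <- rbind(cbind(idx(i, k), idx(ip, k), idx(ip, k + 1L)),
             cbind(idx(i, k), idx(ip, k + 1L), idx(i, k + 1L)))
  # cap fans
  cb <- nrow(v) + 1L; ct <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, -height / 2), c(0, 0, height / 2))
  i <- seq_len(n_theta); ip <- i %% n_theta + 1L
  f <- rbind(f, cbind(cb, idx(ip, 1L), idx(i, 1L)),
             cbind(ct, idx(i, n_z), idx(ip, n_z)))
  m <- triangle_mesh(v, f)
  if (mesh_volume(m, signed = TRUE) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' @rdname mesh_icosphere
#' @param ring_radius,tube_radius torus major and minor radii (mm).
#' @param n_ring,n_tube sampling counts around the ring and the tube.
#' @export
mesh_torus <- function(ring_radius = 2, tube_radius = 0.7, n_ring = 64, n_tube = 32) {
  u <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  w <- seq(0, 2 * pi, length.out = n_tube + 1L)[-(n_tube + 1L)]
  uu <- rep(u, times = n_tube); ww <- rep(w, each = n_ring)
  v <- cbind((ring_radius + tube_radius * cos(ww)) * cos(uu),
             (ring_radius + tube_radius * cos(ww)) * sin(uu),
             tube_radius * sin(ww))
  idx <- function(i, k) (k - 1L) * n_ring + i
  i <- rep(seq_len(n_ring), times = n_tube)
  k <- rep(seq_len(n_tube), each = n_ring)
  ip <- i %% n_ring + 1L; kp <- (k %% n_tube) + 1L
  f <- rbind(cbind(idx(i, k), idx(ip, k), idx(ip, kp)),
             cbind(idx(i, k), idx(ip, kp), idx(i, kp)))
  m <- triangle_mesh(v, f)
  if (mesh_volume(m, signed = TRUE) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' @rdname mesh_icosphere
#' @param nx,ny grid resolution of the plane patch (in the z = 0 plane).
#' @param extent half-width of the patch (mm).
#' @export
mesh_plane <- function(nx = 15, ny = 15, extent = 1) {
  xs <- seq(-extent, extent, length.out = nx)
  ys <- seq(-extent, extent, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, k) (k - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  k <- rep(seq_len(ny - 1L), each = nx - 1L)
  # upward (+z) orientation
  f <- rbind(cbind(idx(i, k), idx(i + 1L, k), idx(i + 1L, k + 1L)),
             cbind(idx(i, k), idx(i + 1L, k + 1L), idx(i, k + 1L)))
  triangle_mesh(v, f)
}

#' Axis-angle rotation matrix
#' @param axis rotation axis (any nonzero 3-vector).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_,        a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[1] * a[2] * C + a[3] * s, a[2]^2 * C + c_,        a[2] * a[3] * C - a[1] * s,
           a[1] * a[3] * C - a[2] * s, a[2] * a[3] * C + a[1] * s, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}
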