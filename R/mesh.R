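#' Triangular surface meshes
#'
#' A `surface_mesh` holds one glomerulus surface: an `n x 3` matrix of vertex
#' positions in micrometres (columns `x`, `y`, `z`) and an `m x 3` integer
#' matrix of 1-based vertex indices per triangle. Meshes produced by
#' [mesh_from_label()] are consistently oriented with outward normals.
#'
#' @param vertices Numeric `n x 3` matrix of vertex coordinates in um.
#' @param triangles Integer `m x 3` matrix of vertex indices (1-based).
#' @return A `surface_mesh` object.
#' @export
#' @examples
#' m <- mesh_cube(side = 2)
#' mesh_volume(m)  # 8
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3L) abort("`vertices` must be an n x 3 matrix.")
  if (!all(is.finite(vertices))) abort("vertex coordinates must be finite.")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    abort("triangle indices out of range.")
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (mesh_is_closed(x)) "closed" else "open"))
  invisible(x)
}

# directed edges as a 3m x 2 matrix (a -> b per triangle winding)
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  rbind(tr[, c(1, 2), drop = FALSE],
        tr[, c(2, 3), drop = FALSE],
        tr[, c(3, 1), drop = FALSE])
}

# undirected boundary edges: edges used by exactly one triangle
boundary_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  n1 <- nrow(mesh$vertices) + 1
  key <- pmin(e[, 1], e[, 2]) * n1 + pmax(e[, 1], e[, 2])
  single <- !(key %in% key[duplicated(key)])
  e[single, , drop = FALSE]
}

#' @rdname surface_mesh
#' @param mesh A `surface_mesh`.
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(FALSE)
  nrow(boundary_edges(mesh)) == 0L
}

#' @rdname surface_mesh
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# signed volume of origin tetrahedra; positive for outward orientation
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  p0 <- v[tr[, 1], , drop = FALSE]
  p1 <- v[tr[, 2], , drop = FALSE]
  p2 <- v[tr[, 3], , drop = FALSE]
  sum(p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
      p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
      p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' The volume enclosed by a closed, consistently oriented triangular surface,
#' computed by the divergence theorem as the sum of signed tetrahedra spanned
#' by each triangle and the origin. The result is translation-invariant and
#' returned in cubic micrometres.
#'
#' @param mesh A closed [surface_mesh()]; see [ensure_closed()].
#' @return Volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  if (!mesh_is_closed(mesh))
    abort("mesh is not watertight; run ensure_closed() first.")
  abs(mesh_signed_volume(mesh))
}

# volume centroid of a closed mesh (divergence theorem, per-tet weighting)
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  p0 <- v[tr[, 1], , drop = FALSE]
  p1 <- v[tr[, 2], , drop = FALSE]
  p2 <- v[tr[, 3], , drop = FALSE]
  vol6 <- p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
          p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
          p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])
  ctr <- (p0 + p1 + p2) / 4  # 4th tet vertex is the origin
  tot <- sum(vol6)
  if (abs(tot) < 1e-12) abort("degenerate mesh: zero enclosed volume.")
  colSums(ctr * vol6) / tot
}

# rigid transform helper used by tests and the morphometry invariances
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, -as.numeric(translation))
  surface_mesh(v, mesh$triangles)
}

#' Analytic mesh primitives
#'
#' Reference meshes used for validation and as morphometry fixtures: an
#' axis-aligned cube, a subdivided icosahedron ("icosphere") and a capsule
#' (cylinder with a hemispherical cap, optionally an open base). All are
#' consistently oriented with outward normals.
#'
#' @param side,radius,length Dimensions in um (`length` is the cylindrical
#'   part of the capsule, which points along +z from the base at the origin).
#' @param subdivisions Number of 4-to-1 triangle subdivisions of the
#'   icosahedron (3 gives 1280 triangles).
#' @param center Centre of the solid in um.
#' @param open_base For `mesh_capsule()`, leave the base disc open (one
#'   boundary loop), mimicking a neck cut from its attachment.
#' @param rings,segments Capsule tessellation density.
#' @return A [surface_mesh()].
#' @export
mesh_cube <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, -as.numeric(center))
  # 12 triangles, outward orientation
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  surface_mesh(v, tr)
}

#' @rdname mesh_cube
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    newtr <- matrix(0L, nrow(tr) * 4, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    for (t in seq_len(nrow(tr))) {
      a <- tr[t, 1]; b <- tr[t, 2]; cc <- tr[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newtr[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                          c(cc, ca, bc), c(ab, bc, ca))
    }
    tr <- newtr
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, -as.numeric(center))
  surface_mesh(v, tr)
}

#' @rdname mesh_cube
#' @export
mesh_capsule <- function(radius = 10, length = 50, segments = 32, rings = 16,
                         open_base = FALSE, center = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  verts <- NULL
  rows <- list()
  add_row <- function(r, z) {
    base <- nrow(verts %||% matrix(0, 0, 3))
    verts <<- rbind(verts, cbind(r * cos(th), r * sin(th), z))
    base + seq_len(segments)
  }
  # cylinder wall from z=0 to z=length, then hemispherical cap
  zs <- seq(0, length, length.out = rings + 1)
  for (z in zs) rows[[length(rows) + 1]] <- add_row(radius, z)
  ph <- seq(0, pi / 2, length.out = rings + 1)[-1]
  for (p in ph[-length(ph)])
    rows[[length(rows) + 1]] <- add_row(radius * cos(p), length + radius * sin(p))
  verts <- rbind(verts, c(0, 0, length + radius))  # apex
  apex <- nrow(verts)
  tr <- NULL
  for (i in seq_len(length(rows) - 1)) {
    a <- rows[[i]]; b <- rows[[i + 1]]
    nxt <- c(2:segments, 1)
    tr <- rbind(tr,
                cbind(a, a[nxt], b[nxt]),
                cbind(a, b[nxt], b))
  }
  top <- rows[[length(rows)]]
  nxt <- c(2:segments, 1)
  tr <- rbind(tr, cbind(top, top[nxt], apex))
  if (!open_base) {
    verts <- rbind(verts, c(0, 0, 0))
    bc <- nrow(verts)
    bot <- rows[[1]]
    tr <- rbind(tr, cbind(bot[nxt], bot, bc))
  }
  verts <- sweep(verts, 2, -as.numeric(center))
  surface_mesh(verts, tr)
}
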