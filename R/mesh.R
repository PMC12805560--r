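#' Triangle-mesh primitives
#'
#' Meshes are plain lists of class `triangle_mesh` with `vertices` (n x 3
#' numeric, Angstrom), `triangles` (m x 3 integer, 1-based), and `colors`
#' (n x 3 RGB in `[0, 1]`). Every primitive is built watertight with
#' consistent outward winding, so exported models are printable and render
#' correctly from any side.
#'
#' @name triangle-mesh
#' @keywords internal
NULL

new_mesh <- function(vertices, triangles, colors) {
  structure(list(vertices = vertices, triangles = triangles, colors = colors),
            class = "triangle_mesh")
}

empty_mesh <- function() {
  new_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
           matrix(numeric(0), 0, 3))
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Build a UV sphere mesh
#'
#' Latitude/longitude tessellation with two pole vertices and `lat - 1`
#' rings of `lon` vertices: `lon * (lat - 1) + 2` vertices and
#' `2 * lon * (lat - 1)` triangles. The polar axis is +Y.
#'
#' @param center Length-3 numeric center (Angstrom).
#' @param radius Sphere radius, `> 0`.
#' @param lat Number of latitude bands, `>= 2`.
#' @param lon Number of longitude segments, `>= 3`.
#' @param color RGB triple in `[0, 1]` applied to every vertex.
#' @return A `triangle_mesh`.
#' @examples
#' m <- make_uv_sphere(c(0, 0, 0), 1, lat = 3, lon = 4)
#' nrow(m$vertices) # 10
#' @export
make_uv_sphere <- function(center, radius, lat, lon, color = c(0.5, 0.5, 0.5)) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius <= 0) {
    abort_mf("molforge_bad_geometry_param", "sphere radius must be positive")
  }
  if (lat < 2 || lon < 3) {
    abort_mf("molforge_bad_geometry_param",
             "sphere tessellation needs lat >= 2 and lon >= 3")
  }
  lat <- as.integer(lat); lon <- as.integer(lon)
  unit <- unit_sphere(lat, lon)
  verts <- unit$vertices * radius
  verts <- sweep(verts, 2, center, "+")
  new_mesh(verts, unit$triangles,
           matrix(rep(color, each = nrow(verts)), ncol = 3))
}

# Cached unit-sphere templates: atoms reuse one tessellation per style, so
# sphere construction in large batches is a scale-and-shift.
.mesh_cache <- new.env(parent = emptyenv())

unit_sphere <- function(lat, lon) {
  key <- paste0("s", lat, "x", lon)
  cached <- .mesh_cache[[key]]
  if (!is.null(cached)) return(cached)

  n_ring <- lat - 1L
  phi <- pi * seq_len(n_ring) / lat
  theta <- 2 * pi * (seq_len(lon) - 1L) / lon
  ring_y <- rep(cos(phi), each = lon)
  ring_s <- rep(sin(phi), each = lon)
  vx <- ring_s * cos(rep(theta, n_ring))
  vz <- ring_s * sin(rep(theta, n_ring))
  vertices <- rbind(c(0, 1, 0), cbind(vx, ring_y, vz), c(0, -1, 0))
  dimnames(vertices) <- NULL

  ring_idx <- function(i, j) 1L + (i - 1L) * lon + ((j - 1L) %% lon) + 1L
  tris <- matrix(0L, 2L * lon * n_ring, 3L)
  t <- 0L
  for (j in seq_len(lon)) { # top cap, CCW from outside
    t <- t + 1L
    tris[t, ] <- c(1L, ring_idx(1L, j), ring_idx(1L, j + 1L))
  }
  if (n_ring > 1L) {
    for (i in seq_len(n_ring - 1L)) {
      for (j in seq_len(lon)) {
        a <- ring_idx(i, j); b <- ring_idx(i, j + 1L)
        c_ <- ring_idx(i + 1L, j); d <- ring_idx(i + 1L, j + 1L)
        t <- t + 1L; tris[t, ] <- c(a, c_, b)
        t <- t + 1L; tris[t, ] <- c(b, c_, d)
      }
    }
  }
  south <- nrow(vertices)
  for (j in seq_len(lon)) {
    t <- t + 1L
    tris[t, ] <- c(south, ring_idx(n_ring, j + 1L), ring_idx(n_ring, j))
  }
  tris <- tris[, c(1L, 3L, 2L), drop = FALSE] # outward winding
  out <- list(vertices = vertices, triangles = tris)
  .mesh_cache[[key]] <- out
  out
}

#' Build a capped cylinder mesh
#'
#' A closed cylinder from `p0` to `p1`: two rings of `segments` vertices
#' plus two cap-center vertices (`2 * segments + 2` vertices,
#' `4 * segments` triangles).
#'
#' @param p0,p1 Length-3 numeric endpoints (Angstrom); must be distinct.
#' @param radius Cylinder radius, `> 0`.
#' @param segments Number of circumferential segments, `>= 3`.
#' @param color RGB triple applied to every vertex.
#' @return A `triangle_mesh`.
#' @examples
#' m <- make_cylinder(c(0, 0, 0), c(0, 0, 1), 0.1, segments = 4)
#' nrow(m$triangles) # 16
#' @export
make_cylinder <- function(p0, p1, radius, segments, color = c(0.75, 0.75, 0.75)) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (!is.finite(len) || len <= 1e-9) {
    abort_mf("molforge_bad_geometry_param", "cylinder endpoints coincide")
  }
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius <= 0) {
    abort_mf("molforge_bad_geometry_param", "cylinder radius must be positive")
  }
  if (segments < 3) {
    abort_mf("molforge_bad_geometry_param", "cylinder needs >= 3 segments")
  }
  segments <- as.integer(segments)
  w <- axis / len
  u <- perpendicular_unit(w)
  v <- cross3(w, u)

  theta <- 2 * pi * (seq_len(segments) - 1L) / segments
  circ <- outer(cos(theta), u) + outer(sin(theta), v)
  ring0 <- sweep(circ * radius, 2, p0, "+")
  ring1 <- sweep(circ * radius, 2, p1, "+")
  vertices <- rbind(ring0, ring1, p0, p1)
  dimnames(vertices) <- NULL

  i0 <- seq_len(segments)
  i0n <- c(i0[-1], i0[1])
  i1 <- i0 + segments
  i1n <- c(i1[-1], i1[1])
  c0 <- 2L * segments + 1L
  c1 <- 2L * segments + 2L
  side <- rbind(cbind(i0, i1, i0n), cbind(i0n, i1, i1n))
  cap0 <- cbind(rep(c0, segments), i0, i0n)      # faces -axis
  cap1 <- cbind(rep(c1, segments), i1n, i1)      # faces +axis
  tris <- rbind(side, cap0, cap1)[, c(1L, 3L, 2L), drop = FALSE] # outward winding
  dimnames(tris) <- NULL
  storage.mode(tris) <- "integer"

  new_mesh(vertices, tris,
           matrix(rep(color, each = nrow(vertices)), ncol = 3))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic unit vector perpendicular to w.
perpendicular_unit <- function(w) {
  e <- if (abs(w[1]) <= abs(w[2]) && abs(w[1]) <= abs(w[3])) c(1, 0, 0)
  else if (abs(w[2]) <= abs(w[3])) c(0, 1, 0)
  else c(0, 0, 1)
  u <- cross3(w, e)
  u / sqrt(sum(u^2))
}

#' Merge triangle meshes into one
#'
#' Concatenates vertices and colors and re-offsets triangle indices. An
#' empty list yields an empty mesh.
#'
#' @param parts List of `triangle_mesh` objects.
#' @return A single `triangle_mesh`.
#' @export
merge_meshes <- function(parts) {
  parts <- parts[vapply(parts, function(p) nrow(p$vertices) > 0, logical(1))]
  if (length(parts) == 0L) return(empty_mesh())
  if (length(parts) == 1L) return(parts[[1]])
  counts <- vapply(parts, function(p) nrow(p$vertices), integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  tris <- do.call(rbind, lapply(seq_along(parts), function(k) {
    parts[[k]]$triangles + offsets[k]
  }))
  new_mesh(
    do.call(rbind, lapply(parts, `[[`, "vertices")),
    tris,
    do.call(rbind, lapply(parts, `[[`, "colors"))
  )
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh A `triangle_mesh`.
#' @return List with `min` and `max` length-3 vectors; an empty mesh gives
#'   a zero box at the origin.
#' @export
mesh_bounds <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) {
    return(list(min = c(0, 0, 0), max = c(0, 0, 0)))
  }
  list(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

translate_mesh <- function(mesh, v) {
  if (nrow(mesh$vertices) > 0) {
    mesh$vertices <- sweep(mesh$vertices, 2, v, "+")
  }
  mesh
}

#' Check that a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two triangles, with
#' opposite orientation (each directed edge appears once).
#'
#' @param mesh A `triangle_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  directed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  keys <- paste(directed[, 1], directed[, 2])
  rkeys <- paste(directed[, 2], directed[, 1])
  !anyDuplicated(keys) && setequal(keys, rkeys)
}

# Signed volume via the divergence theorem; positive iff winding is
# outward for a closed mesh.
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  ab <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  ac <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cr^2))
}
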