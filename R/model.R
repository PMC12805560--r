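#' Build a colored mesh model of a molecule
#'
#' Assembles the triangle mesh for one molecule in the representation given
#' by `style$kind`:
#'
#' * `space_filling`: one sphere per atom at its van der Waals radius; no
#'   bond geometry.
#' * `ball_and_stick`: one sphere per atom at `atom_scale * vdw`; each bond
#'   of order k contributes k parallel sticks, each split at the bond
#'   midpoint into two half-cylinders colored like the nearer atom.
#' * `building_kit`: one sphere per atom at `atom_scale * 2 * covalent`;
#'   each bond of order k contributes k uniform sticks in the kit's neutral
#'   bond color.
#'
#' Parallel sticks of multiple bonds are offset perpendicular to the bond
#' axis, in the plane spanned by the bond and its first non-collinear
#' neighbor atom (so double bonds stay in the ring or substituent plane),
#' with an arbitrary perpendicular as fallback.
#'
#' @param graph A `molecule_graph`.
#' @param conformer A `conformer` aligned with `graph` (from
#'   [embed_conformer()]).
#' @param style A `style_set` from [default_style()].
#' @return A single merged `triangle_mesh`.
#' @examples
#' g <- add_hydrogens(parse_smiles("CO"))
#' m <- build_model(g, embed_conformer(g), default_style("space_filling"))
#' @export
build_model <- function(graph, conformer, style = default_style()) {
  merge_meshes(model_primitives(graph, conformer, style))
}

# The un-merged primitive list (one sphere per atom, one cylinder per stick
# or half-stick); exposed internally so tests can count primitives.
model_primitives <- function(graph, conformer, style) {
  stopifnot(inherits(graph, "molecule_graph"), inherits(conformer, "conformer"))
  if (!inherits(style, "style_set")) {
    abort_mf("molforge_style_error", "style must be a style_set from default_style()")
  }
  X <- conformer$coords
  if (nrow(X) != nrow(graph$atoms)) {
    abort_mf("molforge_bad_param", "conformer is not aligned with the graph")
  }
  kind <- style$kind
  n <- nrow(graph$atoms)

  el_styles <- lapply(unique(graph$atoms$element), function(e) style_element(style, e))
  names(el_styles) <- unique(graph$atoms$element)

  parts <- vector("list", 0L)
  for (a in seq_len(n)) {
    es <- el_styles[[graph$atoms$element[a]]]
    radius <- switch(kind,
      space_filling = es$vdw,
      ball_and_stick = style$atom_scale * es$vdw,
      building_kit = style$atom_scale * 2 * es$covalent
    )
    parts[[length(parts) + 1L]] <- make_uv_sphere(
      X[a, ], radius, style$sphere_lat, style$sphere_lon,
      c(es$r, es$g, es$b))
  }

  if (kind != "space_filling" && nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds$a[k]; b <- graph$bonds$b[k]
      order <- graph$bonds$order[k]
      pa <- X[a, ]; pb <- X[b, ]
      perp <- bond_perpendicular(graph, X, a, b)
      offsets <- (seq_len(order) - (order + 1) / 2) * style$multi_bond_offset
      for (off in offsets) {
        q0 <- pa + perp * off
        q1 <- pb + perp * off
        if (kind == "building_kit") {
          parts[[length(parts) + 1L]] <- make_cylinder(
            q0, q1, style$bond_radius, style$cyl_segments, style$bond_color)
        } else {
          mid <- (q0 + q1) / 2
          ea <- el_styles[[graph$atoms$element[a]]]
          eb <- el_styles[[graph$atoms$element[b]]]
          parts[[length(parts) + 1L]] <- make_cylinder(
            q0, mid, style$bond_radius, style$cyl_segments, c(ea$r, ea$g, ea$b))
          parts[[length(parts) + 1L]] <- make_cylinder(
            mid, q1, style$bond_radius, style$cyl_segments, c(eb$r, eb$g, eb$b))
        }
      }
    }
  }
  parts
}

# Unit vector perpendicular to bond a-b, preferring the plane through the
# first non-collinear neighbor of either end.
bond_perpendicular <- function(graph, X, a, b) {
  axis <- X[b, ] - X[a, ]
  axis <- axis / sqrt(sum(axis^2))
  nbrs <- c(
    graph$bonds$b[graph$bonds$a == a], graph$bonds$a[graph$bonds$b == a],
    graph$bonds$b[graph$bonds$a == b], graph$bonds$a[graph$bonds$b == b]
  )
  nbrs <- setdiff(nbrs, c(a, b))
  for (m in nbrs) {
    v <- X[m, ] - X[a, ]
    cr <- cross3(axis, v)
    ncr <- sqrt(sum(cr^2))
    if (ncr > 1e-6) {
      # in-plane perpendicular: axis x (axis x v) points within the a-b-m plane
      p <- cross3(cr / ncr, axis)
      return(p / sqrt(sum(p^2)))
    }
  }
  perpendicular_unit(axis)
}
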