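#' Place molecular models side by side in a labeled scene
#'
#' Batch requests are laid out on a grid of `ceiling(sqrt(k))` columns in
#' the XY plane (columns along +X, rows stacked downward along -Y), in input
#' order, with at least `spacing` Angstrom of clearance between
#' bounding boxes. When labels are enabled, each model gets a stroke-font
#' label with its input string placed below its bounding box, facing +Z.
#' A single model is centered at the origin.
#'
#' @param models List of models, each a list with `name` (the input SMILES
#'   or trivial name) and `mesh` (a `triangle_mesh`).
#' @param spacing Minimum clearance between model bounding boxes, Angstrom.
#' @param with_labels Draw label meshes under each model?
#' @param label_height Capital height of the label text, Angstrom.
#' @param label_gap Gap between the model's bounding box and the label top,
#'   Angstrom.
#' @param ncols Number of grid columns; default `ceiling(sqrt(k))`.
#' @return A `scene`: list of `nodes` (each with `mesh`, `label`,
#'   `translation`, `name`) and `bounds`.
#' @examples
#' g <- add_hydrogens(parse_smiles("CO"))
#' m <- build_model(g, embed_conformer(g))
#' sc <- layout_grid(list(list(name = "CO", mesh = m)))
#' @export
layout_grid <- function(models, spacing = 2.0, with_labels = TRUE,
                        label_height = 1.0, label_gap = 0.5, ncols = NULL) {
  if (length(models) == 0L) {
    abort_mf("molforge_empty_scene", "no models to lay out")
  }
  if (!is.numeric(spacing) || spacing < 0) {
    abort_mf("molforge_bad_param", "spacing must be >= 0")
  }
  k <- length(models)
  ncols <- if (is.null(ncols)) ceiling(sqrt(k)) else as.integer(ncols)

  prepared <- lapply(models, function(mod) {
    if (is.null(mod$name) || !nzchar(mod$name)) {
      abort_mf("molforge_bad_param", "every model needs a non-empty name")
    }
    bb <- mesh_bounds(mod$mesh)
    label <- NULL
    if (with_labels) {
      label <- make_label_mesh(mod$name, label_height)
      ctr <- (bb$min + bb$max) / 2
      # baseline so the label's top sits label_gap below the model box
      label <- translate_mesh(label, c(ctr[1], bb$min[2] - label_gap - label_height, ctr[3]))
      lb <- mesh_bounds(label)
      bb <- list(min = pmin(bb$min, lb$min), max = pmax(bb$max, lb$max))
    }
    list(mesh = mod$mesh, label = label, bb = bb, name = mod$name)
  })

  exts <- vapply(prepared, function(p) p$bb$max - p$bb$min, numeric(3))
  cell_w <- max(exts[1, ])
  cell_h <- max(exts[2, ])
  pitch_x <- cell_w + spacing
  pitch_y <- cell_h + spacing

  nodes <- vector("list", k)
  for (idx in seq_len(k)) {
    row <- (idx - 1L) %/% ncols
    col <- (idx - 1L) %% ncols
    cell_center <- c(col * pitch_x, -row * pitch_y, 0)
    p <- prepared[[idx]]
    translation <- cell_center - (p$bb$min + p$bb$max) / 2
    nodes[[idx]] <- list(mesh = p$mesh, label = p$label,
                         translation = translation, name = p$name)
  }
  sc <- structure(list(nodes = nodes, bounds = NULL), class = "scene")
  sc$bounds <- scene_bounds(sc)
  sc
}

#' Lay out several representations of one molecule side by side
#'
#' Builds the requested representation kinds from the *same* conformer and
#' places them in a single row, so building-kit, ball-and-stick and
#' space-filling versions of a molecule can be compared atom for atom.
#' Node names are `"<smiles>:<kind>"`.
#'
#' @param graph A `molecule_graph`.
#' @param conformer A matching `conformer`.
#' @param kinds Character vector of representation kinds.
#' @param base_style A `style_set` providing tessellation, bond and offset
#'   parameters; each kind keeps its own default atom proportions.
#' @param spacing,with_labels Passed to [layout_grid()].
#' @return A `scene` with one node per kind.
#' @export
layout_representations <- function(graph, conformer,
                                   kinds = c("ball_and_stick", "space_filling", "building_kit"),
                                   base_style = default_style(),
                                   spacing = 2.0, with_labels = TRUE) {
  if (length(kinds) == 0L) {
    abort_mf("molforge_style_error", "no representation kinds given")
  }
  models <- lapply(kinds, function(kind) {
    st <- default_style(kind,
                        bond_radius = NULL,
                        bond_color = base_style$bond_color,
                        multi_bond_offset = base_style$multi_bond_offset,
                        sphere_lat = base_style$sphere_lat,
                        sphere_lon = base_style$sphere_lon,
                        cyl_segments = base_style$cyl_segments)
    st$element_table <- base_style$element_table
    list(name = paste0(graph$source_smiles, ":", st$kind),
         mesh = build_model(graph, conformer, st))
  })
  layout_grid(models, spacing = spacing, with_labels = with_labels,
              ncols = length(models))
}

#' Exact axis-aligned bounds of a scene
#'
#' Minimum and maximum over all translated vertices of every node's model
#' and label meshes.
#'
#' @param scene A `scene`.
#' @return List with `min` and `max` length-3 vectors.
#' @export
scene_bounds <- function(scene) {
  if (!inherits(scene, "scene") || length(scene$nodes) == 0L) {
    abort_mf("molforge_empty_scene", "scene has no nodes")
  }
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (node in scene$nodes) {
    for (mesh in list(node$mesh, node$label)) {
      if (is.null(mesh) || nrow(mesh$vertices) == 0L) next
      bb <- mesh_bounds(translate_mesh(mesh, node$translation))
      lo <- pmin(lo, bb$min); hi <- pmax(hi, bb$max)
    }
  }
  list(min = lo, max = hi)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d node(s): %s\n", length(x$nodes),
              paste(vapply(x$nodes, `[[`, character(1), "name"), collapse = ", ")))
  invisible(x)
}

# Node mesh with its label merged in and translation applied; what the
# exporters and renderer consume.
node_world_mesh <- function(node, translated = TRUE) {
  mesh <- if (is.null(node$label)) node$mesh else merge_meshes(list(node$mesh, node$label))
  if (translated) translate_mesh(mesh, node$translation) else mesh
}

# Per-node merged (untranslated) mesh plus translation, for exporters that
# keep node transforms.
scene_node_meshes <- function(scene) {
  lapply(scene$nodes, function(node) {
    list(name = node$name,
         mesh = if (is.null(node$label)) node$mesh
                else merge_meshes(list(node$mesh, node$label)),
         translation = node$translation)
  })
}
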