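# Independent oracles used across the suite. These enumerate or count from
# first principles and never call the code paths they check.

# Brute-force UV-grid enumeration: walk every (band, sector) cell of a
# lat x lon sphere grid, collect the distinct grid points (poles collapse)
# and count the triangles each cell contributes.
sphere_grid_oracle <- function(lat, lon) {
  pts <- c("N", "S")
  for (i in seq_len(lat - 1)) {
    for (j in seq_len(lon)) pts <- c(pts, paste(i, j))
  }
  tris <- 0L
  for (i in seq_len(lat)) {
    for (j in seq_len(lon)) {
      tris <- tris + if (i == 1L || i == lat) 1L else 2L
    }
  }
  list(vertices = length(unique(pts)), triangles = tris)
}

# Same idea for a capped cylinder with s circumferential sectors.
cylinder_grid_oracle <- function(s) {
  pts <- c("C0", "C1", paste("r0", seq_len(s)), paste("r1", seq_len(s)))
  tris <- 0L
  for (j in seq_len(s)) {
    tris <- tris + 2L # side quad
    tris <- tris + 1L # bottom cap wedge
    tris <- tris + 1L # top cap wedge
  }
  list(vertices = length(unique(pts)), triangles = tris)
}

# Valence bookkeeping for the linear alkane CnH2n+2: count atoms and bonds
# explicitly rather than through the parser.
alkane_oracle <- function(n) {
  atoms <- n + (2 * n + 2)           # n carbons, 2n+2 hydrogens
  bonds <- (n - 1) + (2 * n + 2)     # C-C chain plus one bond per H
  list(atoms = atoms, bonds = bonds)
}

# Pairwise distances for selected index pairs of a coordinate matrix.
pair_dist <- function(coords, a, b) {
  sqrt(rowSums((coords[a, , drop = FALSE] - coords[b, , drop = FALSE])^2))
}

# A coarse style so unit tests stay fast; tessellation choices here are
# arbitrary and carried through the count arithmetic of each test.
fast_style <- function(kind = "building_kit") {
  default_style(kind, sphere_lat = 3L, sphere_lon = 6L, cyl_segments = 4L)
}

# Build (graph, conformer) once for a SMILES.
embedded <- function(smiles, seed = 0L) {
  g <- add_hydrogens(parse_smiles(smiles))
  list(graph = g, conformer = embed_conformer(g, seed = seed))
}

# Small labeled scene built from one or more SMILES at coarse tessellation.
small_scene <- function(smiles = c("CO"), with_labels = TRUE, seed = 0L) {
  models <- lapply(smiles, function(s) {
    em <- embedded(s, seed = seed)
    list(name = s, mesh = build_model(em$graph, em$conformer, fast_style()))
  })
  layout_grid(models, with_labels = with_labels)
}

# AABB disjointness (strict, in at least one axis) for two bounds lists.
aabbs_disjoint <- function(a, b) {
  any(a$max < b$min) || any(b$max < a$min)
}

scene_node_aabb <- function(scene, k) {
  node <- scene$nodes[[k]]
  mesh <- molforge:::node_world_mesh(node)
  mesh_bounds(mesh)
}
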