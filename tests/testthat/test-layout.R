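simple_model <- function(name, radius = 1) {
  list(name = name, mesh = make_uv_sphere(c(0, 0, 0), radius, 3, 6))
}

test_that("grid layout keeps nodes disjoint with ceil(sqrt(k)) columns", {
  for (k in c(1, 2, 5, 10, 100)) {
    models <- lapply(seq_len(k), function(i) simple_model(paste0("M", i)))
    sc <- layout_grid(models, spacing = 2)
    expect_length(sc$nodes, k)
    # column structure: translations fall on ceil(sqrt(k)) x-positions
    ncols <- ceiling(sqrt(k))
    tx <- vapply(sc$nodes, function(n) n$translation[1], numeric(1))
    expect_lte(length(unique(round(tx, 9))), ncols)
    expect_equal(length(unique(round(tx[seq_len(min(k, ncols))], 9))),
                 min(k, ncols))
    # pairwise-disjoint AABBs (all pairs for small k, a subset for k=100)
    if (k < 2) next
    idx <- utils::combn(min(k, 12), 2)
    boxes <- lapply(seq_len(min(k, 12)), function(i) scene_node_aabb(sc, i))
    for (c_i in seq_len(ncol(idx))) {
      expect_true(aabbs_disjoint(boxes[[idx[1, c_i]]], boxes[[idx[2, c_i]]]),
                  info = sprintf("k=%d pair %d-%d", k, idx[1, c_i], idx[2, c_i]))
    }
  }
})

test_that("a single model is centered at the origin", {
  sc <- layout_grid(list(simple_model("M")), with_labels = FALSE)
  bb <- scene_bounds(sc)
  expect_equal(unname((bb$min + bb$max) / 2), c(0, 0, 0), tolerance = 1e-9)
})

test_that("node order matches input order and layout is deterministic", {
  models <- list(simple_model("CCO"), simple_model("CO"), simple_model("COC"))
  s1 <- layout_grid(models)
  s2 <- layout_grid(models)
  expect_equal(vapply(s1$nodes, `[[`, character(1), "name"),
               c("CCO", "CO", "COC"))
  expect_identical(lapply(s1$nodes, `[[`, "translation"),
                   lapply(s2$nodes, `[[`, "translation"))
})

test_that("labels sit below each model's bounding box", {
  sc <- layout_grid(list(simple_model("CCO"), simple_model("CO")), spacing = 2)
  for (node in sc$nodes) {
    expect_false(is.null(node$label))
    model_bb <- mesh_bounds(node$mesh)
    label_bb <- mesh_bounds(node$label)
    expect_lt(label_bb$max[2], model_bb$min[2])
  }
  sc2 <- layout_grid(list(simple_model("CCO")), with_labels = FALSE)
  expect_null(sc2$nodes[[1]]$label)
})

test_that("empty layouts are rejected", {
  expect_error(layout_grid(list()), class = "molforge_empty_scene")
  expect_error(layout_grid(list(simple_model("A")), spacing = -1),
               class = "molforge_bad_param")
})

test_that("multi-representation layout gives one named node per kind", {
  em <- embedded("COC")
  sc <- layout_representations(em$graph, em$conformer,
                               base_style = fast_style())
  expect_length(sc$nodes, 3)
  expect_equal(vapply(sc$nodes, `[[`, character(1), "name"),
               c("COC:ball_and_stick", "COC:space_filling", "COC:building_kit"))
  sc1 <- layout_representations(em$graph, em$conformer, kinds = "building_kit",
                                base_style = fast_style())
  expect_length(sc1$nodes, 1)
  expect_error(
    layout_representations(em$graph, em$conformer, kinds = "wireframe",
                           base_style = fast_style()),
    class = "molforge_style_error")
})

test_that("label meshes follow the advance-width arithmetic", {
  h <- 1.0
  m2 <- make_label_mesh("CO", h)
  bb <- mesh_bounds(m2)
  advance <- 0.8; glyph_w <- 0.6; stroke <- 0.08
  expect_equal(bb$max[1] - bb$min[1], ((2 - 1) * advance + glyph_w) * h + stroke * h,
               tolerance = 0.05)
  # monotone width and flatness
  m8 <- make_label_mesh("C1CCCCC1", h)
  bb8 <- mesh_bounds(m8)
  expect_gt(bb8$max[1] - bb8$min[1], bb$max[1] - bb$min[1])
  expect_equal(bb8$max[3] - bb8$min[3], 0)
  # undefined characters fall back to a box glyph rather than failing
  expect_gt(nrow(make_label_mesh("~", h)$vertices), 0)
  expect_error(make_label_mesh("", h), class = "molforge_empty_input")
  expect_error(make_label_mesh("C", -1), class = "molforge_bad_geometry_param")
})

test_that("scene bounds are exact, equivariant and contain node bounds", {
  # default tessellation has rings/sectors on every axis, so the unit
  # sphere's box is exactly [-1, 1]^3
  fine <- list(name = "A", mesh = make_uv_sphere(c(0, 0, 0), 1, 12, 24))
  sc <- layout_grid(list(fine), with_labels = FALSE)
  bb <- scene_bounds(sc)
  expect_equal(unname(bb$min), c(-1, -1, -1), tolerance = 1e-9)
  expect_equal(unname(bb$max), c(1, 1, 1), tolerance = 1e-9)

  shifted <- sc
  shifted$nodes[[1]]$translation <- shifted$nodes[[1]]$translation + c(3, -2, 5)
  bb2 <- scene_bounds(shifted)
  expect_equal(unname(bb2$min), unname(bb$min) + c(3, -2, 5), tolerance = 1e-9)

  sc2 <- layout_grid(list(simple_model("A"), simple_model("B")))
  full <- scene_bounds(sc2)
  for (k in 1:2) {
    nb <- scene_node_aabb(sc2, k)
    expect_true(all(nb$min >= full$min - 1e-9) && all(nb$max <= full$max + 1e-9))
  }
})
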