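test_that("space-filling models are one sphere per atom", {
  em <- embedded("C1CCCCC1")
  style <- default_style("space_filling", sphere_lat = 3, sphere_lon = 4)
  m <- build_model(em$graph, em$conformer, style)
  oracle <- sphere_grid_oracle(3, 4)
  expect_equal(nrow(m$vertices), 18 * oracle$vertices) # 18 * 10 = 180
  expect_equal(nrow(m$triangles), 18 * oracle$triangles)
})

test_that("ball-and-stick primitive counts follow atoms + 2 half-bonds per stick", {
  em <- embedded("C1CCCCC1")
  parts <- molforge:::model_primitives(em$graph, em$conformer,
                                       fast_style("ball_and_stick"))
  # 18 atom spheres + 18 single bonds * 2 halves
  expect_length(parts, 18 + 36)

  # ethene: the C=C double bond contributes 2 parallel sticks x 2 halves
  em2 <- embedded("C=C")
  parts2 <- molforge:::model_primitives(em2$graph, em2$conformer,
                                        fast_style("ball_and_stick"))
  # 6 atoms + (2 sticks * 2 halves for C=C) + (4 C-H * 2 halves)
  expect_length(parts2, 6 + 4 + 8)
})

test_that("building-kit models use one uniform stick per bond line", {
  em <- embedded("C=C")
  style <- fast_style("building_kit")
  parts <- molforge:::model_primitives(em$graph, em$conformer, style)
  expect_length(parts, 6 + 2 + 4) # atoms + double-bond sticks + C-H sticks
  # every cylinder is the neutral bond color
  cyl <- parts[-(1:6)]
  for (p in cyl) {
    expect_true(all(p$colors[1, ] == style$bond_color))
  }
})

test_that("all representations share identical atom centers", {
  em <- embedded("COC")
  style <- fast_style()
  sphere_v <- sphere_grid_oracle(3, 6)$vertices
  centers <- lapply(c("building_kit", "ball_and_stick", "space_filling"),
    function(kind) {
      st <- default_style(kind, sphere_lat = 3, sphere_lon = 6, cyl_segments = 4)
      m <- build_model(em$graph, em$conformer, st)
      # vertex means of each atom sphere = atom centers
      t(vapply(seq_len(nrow(em$graph$atoms)), function(a) {
        rows <- ((a - 1) * sphere_v + 1):(a * sphere_v)
        colMeans(m$vertices[rows, ])
      }, numeric(3)))
    })
  expect_equal(centers[[1]], centers[[2]], tolerance = 1e-12)
  expect_equal(centers[[1]], centers[[3]], tolerance = 1e-12)
})

test_that("vertex counts obey the closed-form representation arithmetic", {
  em <- embedded("CCO")
  lat <- 4; lon <- 6; seg <- 5
  sv <- sphere_grid_oracle(lat, lon)$vertices
  cv <- cylinder_grid_oracle(seg)$vertices
  n_at <- nrow(em$graph$atoms)
  n_bonds <- nrow(em$graph$bonds) # all single in ethanol
  sf <- build_model(em$graph, em$conformer,
                    default_style("space_filling", sphere_lat = lat,
                                  sphere_lon = lon, cyl_segments = seg))
  bs <- build_model(em$graph, em$conformer,
                    default_style("ball_and_stick", sphere_lat = lat,
                                  sphere_lon = lon, cyl_segments = seg))
  expect_equal(nrow(sf$vertices), n_at * sv)
  expect_equal(nrow(bs$vertices), n_at * sv + 2 * n_bonds * cv)
})

test_that("every element in the default table renders in its own color", {
  tab <- element_table()
  for (el in tab$element) {
    g <- parse_smiles(paste0("[", el, "]"))
    conf <- embed_conformer(g, seed = 1)
    expect_no_warning(m <- build_model(g, conf, fast_style("space_filling")))
    row <- tab[tab$element == el, ]
    expect_equal(unname(m$colors[1, ]), c(row$r, row$g, row$b), info = el)
  }
})

test_that("unknown elements render with the fallback style and a warning", {
  g <- add_hydrogens(parse_smiles("[Xe]"))
  conf <- embed_conformer(g, seed = 1)
  expect_warning(m <- build_model(g, conf, fast_style("space_filling")),
                 "fallback")
  expect_gt(nrow(m$vertices), 0)
  expect_equal(unname(m$colors[1, ]), c(1.00, 0.41, 0.71))
})

test_that("style validation rejects bad kinds and parameters", {
  expect_error(default_style("wireframe"), class = "molforge_style_error")
  expect_error(default_style("building_kit", atom_scale = 0),
               class = "molforge_style_error")
  expect_error(default_style("building_kit", sphere_lat = 1),
               class = "molforge_style_error")
  em <- embedded("C")
  expect_error(build_model(em$graph, em$conformer, list(kind = "building_kit")),
               class = "molforge_style_error")
})

test_that("style config files override proportions and element entries", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# test overrides",
    "atom_scale = 0.5",
    "bond_radius = 0.2",
    "sphere_lat = 5",
    "bond_color = 0.1, 0.2, 0.3",
    "element.C.color = 0, 1, 0",
    "element.C.vdw = 2.0"
  ), f)
  st <- load_style_config(f, default_style("ball_and_stick"))
  expect_equal(st$atom_scale, 0.5)
  expect_equal(st$bond_radius, 0.2)
  expect_equal(st$sphere_lat, 5L)
  expect_equal(st$bond_color, c(0.1, 0.2, 0.3))
  crow <- st$element_table[st$element_table$element == "C", ]
  expect_equal(unlist(crow[c("r", "g", "b")], use.names = FALSE), c(0, 1, 0))
  expect_equal(crow$vdw, 2.0)
  writeLines("nonsense = abc", f)
  expect_error(load_style_config(f), class = "molforge_style_error")
})
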