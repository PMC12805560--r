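test_that("GLB files carry the mandated container structure", {
  sc <- small_scene()
  f <- withr::local_tempfile(fileext = ".glb")
  write_glb(sc, f)
  con <- file(f, "rb")
  on.exit(close(con))
  expect_equal(rawToChar(readBin(con, "raw", 4)), "glTF")
  header <- readBin(con, "integer", 2, size = 4, endian = "little")
  expect_equal(header[1], 2)          # container version
  expect_equal(header[2], file.info(f)$size)  # declared total length
  json_len <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_equal(json_len %% 4, 0)
  expect_equal(rawToChar(readBin(con, "raw", 4)), "JSON")
})

test_that("GLB round-trip preserves counts, names and coordinates", {
  sc <- small_scene(c("CCO", "CO"))
  f <- withr::local_tempfile(fileext = ".glb")
  write_glb(sc, f)
  r <- read_glb(f)
  expect_equal(r$asset_version, "2.0")
  expect_length(r$nodes, 2)
  nodes <- molforge:::scene_node_meshes(sc)
  for (k in 1:2) {
    expect_equal(r$nodes[[k]]$name, nodes[[k]]$name)
    expect_equal(nrow(r$nodes[[k]]$vertices), nrow(nodes[[k]]$mesh$vertices))
    expect_equal(nrow(r$nodes[[k]]$triangles), nrow(nodes[[k]]$mesh$triangles))
    expect_identical(r$nodes[[k]]$triangles, nodes[[k]]$mesh$triangles)
    # coordinates survive the float32 trip to within 1e-5 after unscaling
    back <- r$nodes[[k]]$vertices / 0.02
    expect_lt(max(abs(back - nodes[[k]]$mesh$vertices)), 1e-5)
    expect_lt(max(abs(r$nodes[[k]]$colors - nodes[[k]]$mesh$colors)), 1e-6)
  }
})

test_that("exported extents scale by meters-per-Angstrom", {
  sc <- small_scene("C1CCCCC1", with_labels = FALSE)
  f <- withr::local_tempfile(fileext = ".glb")
  write_glb(sc, f, export_options(scale = 0.02))
  r <- read_glb(f)
  ang_extent <- scene_bounds(sc)$max - scene_bounds(sc)$min
  m_extent <- apply(r$nodes[[1]]$vertices, 2, max) -
    apply(r$nodes[[1]]$vertices, 2, min)
  expect_equal(unname(m_extent), unname(ang_extent) * 0.02, tolerance = 1e-5)
})

test_that("glTF JSON variant declares version 2.0 and round-trips", {
  sc <- small_scene(c("CCO", "CO"))
  f <- withr::local_tempfile(fileext = ".gltf")
  write_gltf(sc, f)
  json <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(json$asset$version, "2.0")
  expect_equal(vapply(json$nodes, `[[`, character(1), "name"), c("CCO", "CO"))
  r <- read_gltf(f)
  nodes <- molforge:::scene_node_meshes(sc)
  for (k in 1:2) {
    expect_equal(nrow(r$nodes[[k]]$vertices), nrow(nodes[[k]]$mesh$vertices))
    expect_equal(nrow(r$nodes[[k]]$triangles), nrow(nodes[[k]]$mesh$triangles))
  }
})

test_that("an independent glTF reader agrees on the exported geometry", {
  sc <- small_scene("CCO")
  f <- withr::local_tempfile(fileext = ".glb")
  write_glb(sc, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import trimesh\n",
    "s = trimesh.load('", f, "')\n",
    "print(sum(len(g.vertices) for g in s.geometry.values()))\n",
    "print(sum(len(g.faces) for g in s.geometry.values()))\n"
  ))), stdout = TRUE, stderr = FALSE))
  counts <- as.integer(out[nzchar(out)])
  mesh <- molforge:::scene_node_meshes(sc)[[1]]$mesh
  expect_equal(counts[1], nrow(mesh$vertices))
  expect_equal(counts[2], nrow(mesh$triangles))
})

test_that("exporters reject empty scenes uniformly", {
  empty <- structure(list(nodes = list(), bounds = NULL), class = "scene")
  f <- withr::local_tempfile()
  expect_error(write_glb(empty, f), class = "molforge_empty_scene")
  expect_error(write_gltf(empty, f), class = "molforge_empty_scene")
  expect_error(write_usdz(empty, f), class = "molforge_empty_scene")
  expect_error(write_mesh_format(empty, f, "obj"), class = "molforge_empty_scene")
  expect_error(write_mesh_format(empty, f, "stl"), class = "molforge_empty_scene")
  expect_error(render_png(empty, f), class = "molforge_empty_scene")
  expect_error(write_usdz_zip(list(), f), class = "molforge_empty_scene")
})
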