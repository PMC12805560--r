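test_that("sphere and cylinder counts match UV-grid enumeration over a sweep", {
  for (lat in 2:6) {
    for (lon in 3:8) {
      oracle <- sphere_grid_oracle(lat, lon)
      m <- make_uv_sphere(c(0, 0, 0), 1, lat, lon)
      expect_equal(nrow(m$vertices), oracle$vertices,
                   info = sprintf("lat=%d lon=%d", lat, lon))
      expect_equal(nrow(m$triangles), oracle$triangles,
                   info = sprintf("lat=%d lon=%d", lat, lon))
    }
  }
  for (s in 3:8) {
    oracle <- cylinder_grid_oracle(s)
    m <- make_cylinder(c(0, 0, 0), c(0, 0, 1), 0.2, s)
    expect_equal(nrow(m$vertices), oracle$vertices, info = paste("segments", s))
    expect_equal(nrow(m$triangles), oracle$triangles, info = paste("segments", s))
  }
})

test_that("spheres are exact, watertight and outward-wound", {
  m <- make_uv_sphere(c(1, -2, 3), 1.7, 5, 9)
  r <- sqrt(rowSums(sweep(m$vertices, 2, c(1, -2, 3))^2))
  expect_lt(max(abs(r - 1.7)), 1e-9)
  expect_true(mesh_is_watertight(m))
  m0 <- make_uv_sphere(c(0, 0, 0), 1.7, 12, 24)
  vol <- molforge:::mesh_signed_volume(m0)
  expect_gt(vol, 0)
  expect_lt(abs(vol - 4 / 3 * pi * 1.7^3) / (4 / 3 * pi * 1.7^3), 0.05)
  expect_true(all(molforge:::triangle_areas(m) > 1e-9))
})

test_that("cylinders span their axis, watertight with positive volume", {
  p0 <- c(0.5, 1, -2); p1 <- c(1.5, 0, 1)
  m <- make_cylinder(p0, p1, 0.3, 16)
  len <- sqrt(sum((p1 - p0)^2))
  # the two cap centers are the final vertices
  caps <- m$vertices[(nrow(m$vertices) - 1):nrow(m$vertices), ]
  expect_equal(sqrt(sum((caps[2, ] - caps[1, ])^2)), len, tolerance = 1e-12)
  expect_true(mesh_is_watertight(m))
  vol <- molforge:::mesh_signed_volume(m)
  expect_gt(vol, 0)
  expect_true(all(molforge:::triangle_areas(m) > 1e-9))
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(make_uv_sphere(c(0, 0, 0), 0, 3, 4),
               class = "molforge_bad_geometry_param")
  expect_error(make_uv_sphere(c(0, 0, 0), 1, 1, 4),
               class = "molforge_bad_geometry_param")
  expect_error(make_uv_sphere(c(0, 0, 0), 1, 3, 2),
               class = "molforge_bad_geometry_param")
  expect_error(make_cylinder(c(0, 0, 0), c(0, 0, 0), 0.1, 8),
               class = "molforge_bad_geometry_param")
  expect_error(make_cylinder(c(0, 0, 0), c(0, 0, 1), -1, 8),
               class = "molforge_bad_geometry_param")
  expect_error(make_cylinder(c(0, 0, 0), c(0, 0, 1), 0.1, 2),
               class = "molforge_bad_geometry_param")
})

test_that("merge_meshes is identity on one part, empty on none, additive", {
  a <- make_uv_sphere(c(0, 0, 0), 1, 3, 4)
  b <- make_cylinder(c(0, 0, 0), c(0, 0, 1), 0.1, 4)
  expect_identical(merge_meshes(list(a)), a)
  expect_equal(nrow(merge_meshes(list())$vertices), 0)
  m <- merge_meshes(list(a, b))
  expect_equal(nrow(m$vertices), nrow(a$vertices) + nrow(b$vertices))
  expect_equal(nrow(m$triangles), nrow(a$triangles) + nrow(b$triangles))
  # indices re-offset: the merged mesh references only valid vertices
  expect_true(all(m$triangles >= 1 & m$triangles <= nrow(m$vertices)))
  # second part's triangles shifted by the first part's vertex count
  expect_equal(m$triangles[(nrow(a$triangles) + 1):nrow(m$triangles), ],
               b$triangles + nrow(a$vertices))
})
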