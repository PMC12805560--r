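#' Render a scene to PNG with the built-in software rasterizer
#'
#' A deterministic, GPU-free renderer: a perspective camera orbits the
#' scene center at the configured azimuth/elevation and backs off until the
#' scene's bounding sphere fits the frame with the configured margin;
#' triangles are depth-sorted (painter's algorithm) and filled with flat
#' Lambert shading from a single fixed directional light. Identical scene
#' and options give byte-identical files. World coordinates are taken
#' relative to the scene center (quantized), so translating a whole scene
#' does not change the image.
#'
#' @inheritParams write_glb
#' @return `path`, invisibly.
#' @export
render_png <- function(scene, path, options = export_options()) {
  check_scene(scene)
  img <- render_scene_array(scene, options)
  png::writePNG(img, path)
  invisible(path)
}

render_scene_array <- function(scene, options) {
  width <- options$png_size[1]; height <- options$png_size[2]
  az <- options$camera[1] * pi / 180
  el <- options$camera[2] * pi / 180
  margin <- options$camera[3]

  bb <- scene_bounds(scene)
  center <- (bb$min + bb$max) / 2

  meshes <- lapply(scene$nodes, node_world_mesh)
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), integer(1))))
  tris <- do.call(rbind, lapply(seq_along(meshes), function(k) {
    meshes[[k]]$triangles + offs[k]
  }))
  cols <- do.call(rbind, lapply(meshes, `[[`, "colors"))

  # center-relative, quantized world coordinates: global translations cancel
  w <- sweep(verts, 2, center)
  w <- round(w * 131072) / 131072
  radius <- max(sqrt(rowSums(w^2)), 1e-6)

  fov <- 40 * pi / 180
  dist <- radius * margin / sin(fov / 2)

  # camera orbit: azimuth about +Y, then elevation; looks at the origin
  ca <- cos(az); sa <- sin(az); ce <- cos(el); se <- sin(el)
  eye <- dist * c(sa * ce, se, ca * ce)
  fwd <- -eye / sqrt(sum(eye^2))
  right <- cross3(fwd, c(0, 1, 0))
  rl <- sqrt(sum(right^2))
  if (rl < 1e-9) { right <- c(1, 0, 0); rl <- 1 } # looking straight up/down
  right <- right / rl
  up <- cross3(right, fwd)
  V <- rbind(right, up, -fwd) # rows: camera basis; camera looks down -z

  cam <- sweep(w, 2, eye) %*% t(V)

  f <- (height / 2) / tan(fov / 2)
  z <- cam[, 3]
  z[z > -1e-6] <- -1e-6 # clamp anything behind the eye
  px <- f * cam[, 1] / (-z) + width / 2
  py <- -f * cam[, 2] / (-z) + height / 2
  proj <- cbind(px, py)

  # painter's sort: farthest triangle centroid first
  tz <- (z[tris[, 1]] + z[tris[, 2]] + z[tris[, 3]]) / 3
  ord <- order(tz)
  tris <- tris[ord, , drop = FALSE]

  # flat Lambert shading in camera space, light fixed relative to camera
  a <- cam[tris[, 1], , drop = FALSE]
  b <- cam[tris[, 2], , drop = FALSE]
  c_ <- cam[tris[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  nl <- sqrt(rowSums(nrm^2))
  nl[nl == 0] <- 1
  nrm <- nrm / nl
  flip <- nrm[, 3] < 0 # face the camera
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  light <- c(0.35, 0.45, 0.83)
  light <- light / sqrt(sum(light^2))
  lambert <- pmax(0, nrm %*% light)
  shade <- 0.35 + 0.65 * as.vector(lambert)

  tri_col <- (cols[tris[, 1], , drop = FALSE] +
              cols[tris[, 2], , drop = FALSE] +
              cols[tris[, 3], , drop = FALSE]) / 3
  tri_col <- pmin(pmax(tri_col * shade, 0), 1)

  img_vec <- .rasterize_triangles(proj, tris, tri_col, width, height,
                                  c(1, 1, 1))
  array(img_vec, dim = c(height, width, 3))
}
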