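#' Write a scene as OBJ or binary STL
#'
#' The cross-platform mesh formats: Wavefront OBJ (one named `o` object per
#' scene node, `v`/`f` records, 1-based indices) and binary STL (80-byte
#' header, little-endian uint32 triangle count, 50 bytes per triangle).
#' STL carries no color by design. Coordinates are scaled to meters.
#'
#' @inheritParams write_glb
#' @param format `"obj"` or `"stl"`.
#' @return `path`, invisibly.
#' @export
write_mesh_format <- function(scene, path, format, options = export_options()) {
  if (!is.character(format) || length(format) != 1L ||
      !(format %in% c("obj", "stl"))) {
    abort_mf("molforge_unknown_format",
             sprintf("unknown mesh format %s (supported: obj, stl)",
                     dQuote(paste(format, collapse = "/"), q = FALSE)))
  }
  check_scene(scene)
  if (format == "obj") write_obj_impl(scene, path, options)
  else write_stl_impl(scene, path, options)
  invisible(path)
}

write_obj_impl <- function(scene, path, options) {
  nodes <- scene_node_meshes(scene)
  names_out <- sanitize_names(vapply(nodes, `[[`, character(1), "name"))
  lines <- c("# molforge OBJ export")
  offset <- 0L
  for (k in seq_along(nodes)) {
    mesh <- translate_mesh(nodes[[k]]$mesh, nodes[[k]]$translation)
    v <- mesh$vertices * options$scale
    lines <- c(
      lines,
      paste0("o ", names_out[k]),
      sprintf("v %.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", mesh$triangles[, 1] + offset,
              mesh$triangles[, 2] + offset, mesh$triangles[, 3] + offset)
    )
    offset <- offset + nrow(v)
  }
  writeLines(lines, path)
}

write_stl_impl <- function(scene, path, options) {
  nodes <- scene_node_meshes(scene)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "molforge binary STL"))[1:80]
  writeBin(header, con)
  total <- sum(vapply(nodes, function(n) nrow(n$mesh$triangles), integer(1)))
  writeBin(as.integer(total), con, size = 4L, endian = "little")
  for (nd in nodes) {
    mesh <- translate_mesh(nd$mesh, nd$translation)
    v <- mesh$vertices * options$scale
    tr <- mesh$triangles
    a <- v[tr[, 1], , drop = FALSE]
    b <- v[tr[, 2], , drop = FALSE]
    c_ <- v[tr[, 3], , drop = FALSE]
    ab <- b - a; ac <- c_ - a
    nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                 ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                 ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
    nl <- sqrt(rowSums(nrm^2))
    nl[nl == 0] <- 1
    nrm <- nrm / nl
    # 12 float32 per triangle: normal, 3 vertices; then uint16 attribute
    payload <- t(cbind(nrm, a, b, c_))
    for (t_i in seq_len(nrow(tr))) {
      writeBin(as.numeric(payload[, t_i]), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
}

#' Read back an OBJ file written by [write_mesh_format()]
#'
#' @param path An `.obj` file.
#' @return List of nodes, each with `name`, `vertices` (meters) and
#'   `triangles` (1-based, node-local indices).
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- list()
  cur_name <- "default"
  verts <- list(); faces <- list()
  global_offset <- 0L
  flush <- function() {
    if (length(verts) > 0) {
      v <- do.call(rbind, verts)
      f <- if (length(faces) > 0) do.call(rbind, faces) - global_offset
      else matrix(integer(0), 0, 3)
      nodes[[length(nodes) + 1L]] <<- list(name = cur_name, vertices = v,
                                           triangles = f)
      global_offset <<- global_offset + nrow(v)
    }
    verts <<- list(); faces <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "o ")) {
      flush()
      cur_name <- sub("^o ", "", ln)
    } else if (startsWith(ln, "v ")) {
      verts[[length(verts) + 1L]] <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4])
    } else if (startsWith(ln, "f ")) {
      idx <- strsplit(trimws(ln), "\\s+")[[1]][-1]
      faces[[length(faces) + 1L]] <- as.integer(sub("/.*$", "", idx))[1:3]
    }
  }
  flush()
  nodes
}

#' Read the triangle count declared by a binary STL file
#'
#' @param path A binary `.stl` file.
#' @return The uint32 triangle-count field.
#' @export
read_stl_count <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  readBin(con, "integer", 1L, size = 4L, endian = "little")
}
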