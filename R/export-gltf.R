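# glTF 2.0 export: one named mesh node per scene node, float32 positions
# and COLOR_0 vertex colors, uint32 indices, coordinates scaled to meters.
# Written directly against the glTF 2.0 specification; no R binding for the
# format exists.

f32_raw <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
u32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

pad_to <- function(x, n, fill = as.raw(0)) {
  rem <- length(x) %% n
  if (rem == 0L) x else c(x, rep(fill, n - rem))
}

gltf_build <- function(scene, options) {
  check_scene(scene)
  nodes <- scene_node_meshes(scene)
  names_out <- vapply(nodes, `[[`, character(1), "name")

  chunks <- list()
  bin_len <- 0L
  buffer_views <- list()
  accessors <- list()
  meshes <- list()
  gnodes <- list()

  add_view <- function(data, target) {
    buffer_views[[length(buffer_views) + 1L]] <<- list(
      buffer = 0L, byteOffset = bin_len, byteLength = length(data),
      target = target)
    padded <- pad_to(data, 4L)
    chunks[[length(chunks) + 1L]] <<- padded
    bin_len <<- bin_len + length(padded)
    length(buffer_views) - 1L
  }

  for (k in seq_along(nodes)) {
    mesh <- nodes[[k]]$mesh
    verts <- mesh$vertices * options$scale
    nv <- nrow(verts)
    pos_view <- add_view(f32_raw(as.vector(t(verts))), 34962L)
    col_view <- add_view(f32_raw(as.vector(t(mesh$colors))), 34962L)
    idx_view <- add_view(u32_raw(as.vector(t(mesh$triangles)) - 1L), 34963L)

    accessors[[length(accessors) + 1L]] <- list(
      bufferView = pos_view, componentType = 5126L, count = nv, type = "VEC3",
      min = as.numeric(apply(verts, 2, min)), max = as.numeric(apply(verts, 2, max)))
    pos_acc <- length(accessors) - 1L
    accessors[[length(accessors) + 1L]] <- list(
      bufferView = col_view, componentType = 5126L, count = nv, type = "VEC3")
    col_acc <- length(accessors) - 1L
    accessors[[length(accessors) + 1L]] <- list(
      bufferView = idx_view, componentType = 5125L,
      count = 3L * nrow(mesh$triangles), type = "SCALAR")
    idx_acc <- length(accessors) - 1L

    meshes[[length(meshes) + 1L]] <- list(
      name = names_out[k],
      primitives = list(list(
        attributes = list(POSITION = pos_acc, COLOR_0 = col_acc),
        indices = idx_acc, mode = 4L)))
    gnodes[[length(gnodes) + 1L]] <- list(
      name = names_out[k], mesh = length(meshes) - 1L,
      translation = as.numeric(nodes[[k]]$translation * options$scale))
  }

  bin <- do.call(c, c(chunks, list(raw(0))))
  json <- list(
    asset = list(version = "2.0", generator = "molforge"),
    scene = 0L,
    scenes = list(list(nodes = I(seq_along(gnodes) - 1L))),
    nodes = gnodes,
    meshes = meshes,
    accessors = accessors,
    bufferViews = buffer_views,
    buffers = list(list(byteLength = length(bin)))
  )
  list(json = json, bin = bin)
}

gltf_json_raw <- function(json) {
  charToRaw(as.character(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA)))
}

#' Write a scene as binary glTF (GLB)
#'
#' Produces a single-file glTF 2.0 binary container: `"glTF"` magic,
#' version 2, 4-byte-aligned JSON and BIN chunks, one named mesh node per
#' scene node with per-vertex colors, coordinates in meters (Y-up).
#'
#' @param scene A `scene` from [layout_grid()] or [layout_representations()].
#' @param path Output file path.
#' @param options An [export_options()] list.
#' @return `path`, invisibly.
#' @export
write_glb <- function(scene, path, options = export_options()) {
  parts <- gltf_build(scene, options)
  json_raw <- pad_to(gltf_json_raw(parts$json), 4L, fill = charToRaw(" "))
  bin_raw <- pad_to(parts$bin, 4L)
  total <- 12L + 8L + length(json_raw) + 8L + length(bin_raw)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("glTF"), con)
  writeBin(as.integer(c(2L, total)), con, size = 4L, endian = "little")
  writeBin(as.integer(length(json_raw)), con, size = 4L, endian = "little")
  writeBin(charToRaw("JSON"), con)
  writeBin(json_raw, con)
  writeBin(as.integer(length(bin_raw)), con, size = 4L, endian = "little")
  writeBin(c(charToRaw("BIN"), as.raw(0)), con)
  writeBin(bin_raw, con)
  invisible(path)
}

#' Write a scene as glTF (JSON plus external binary buffer)
#'
#' Same content contract as [write_glb()], but as a `.gltf` JSON file
#' referencing a sibling `.bin` buffer.
#'
#' @inheritParams write_glb
#' @return `path`, invisibly. The buffer is written next to it with the
#'   extension `.bin`.
#' @export
write_gltf <- function(scene, path, options = export_options()) {
  parts <- gltf_build(scene, options)
  bin_path <- paste0(sub("\\.gltf$", "", path), ".bin")
  parts$json$buffers[[1]]$uri <- basename(bin_path)
  writeBin(gltf_json_raw(parts$json), path)
  writeBin(parts$bin, bin_path)
  invisible(path)
}

#' Read back a GLB file written by [write_glb()]
#'
#' Minimal glTF 2.0 binary reader used to verify exports: returns per-node
#' geometry (vertices in meters, 1-based triangles, vertex colors).
#'
#' @param path A `.glb` file.
#' @return List with `asset_version` and `nodes`; each node has `name`,
#'   `translation`, `vertices`, `triangles`, `colors`.
#' @export
read_glb <- function(path) {
  x <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(x[1:4]) != "glTF") abort_mf("molforge_io_error", "not a GLB file")
  version <- read_u32(x, 5L)
  json_len <- read_u32(x, 13L)
  stopifnot(rawToChar(x[17:20]) == "JSON")
  json <- jsonlite::fromJSON(rawToChar(x[21:(20 + json_len)]),
                             simplifyVector = FALSE)
  bin <- raw(0)
  bin_at <- 21L + json_len
  if (bin_at < length(x)) {
    bin_len <- read_u32(x, bin_at)
    stopifnot(rawToChar(x[(bin_at + 4L):(bin_at + 6L)]) == "BIN")
    bin <- x[(bin_at + 8L):(bin_at + 7L + bin_len)]
  }
  gltf_decode(json, bin, version)
}

#' Read back a glTF file written by [write_gltf()]
#'
#' @param path A `.gltf` file; its buffer uri is resolved relative to it.
#' @return Same structure as [read_glb()].
#' @export
read_gltf <- function(path) {
  json <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bin <- raw(0)
  if (length(json$buffers) > 0 && !is.null(json$buffers[[1]]$uri)) {
    bin_path <- file.path(dirname(path), json$buffers[[1]]$uri)
    bin <- readBin(bin_path, "raw", file.info(bin_path)$size)
  }
  gltf_decode(json, bin, 2)
}

gltf_decode <- function(json, bin, version) {
  read_accessor <- function(ai) {
    acc <- json$accessors[[ai + 1L]]
    bv <- json$bufferViews[[acc$bufferView + 1L]]
    off <- if (is.null(bv$byteOffset)) 0L else bv$byteOffset
    off <- off + if (is.null(acc$byteOffset)) 0L else acc$byteOffset
    ncomp <- switch(acc$type, SCALAR = 1L, VEC3 = 3L, VEC2 = 2L, VEC4 = 4L)
    count <- acc$count * ncomp
    chunk <- bin[(off + 1L):(off + 4L * count)]
    if (acc$componentType == 5126L) {
      vals <- readBin(chunk, "numeric", count, size = 4L, endian = "little")
    } else if (acc$componentType == 5125L) {
      vals <- readBin(chunk, "integer", count, size = 4L, endian = "little")
    } else {
      abort_mf("molforge_io_error", "unsupported glTF component type")
    }
    if (ncomp > 1L) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
  }
  nodes <- lapply(json$nodes, function(nd) {
    mesh <- json$meshes[[nd$mesh + 1L]]
    prim <- mesh$primitives[[1]]
    verts <- read_accessor(prim$attributes$POSITION)
    cols <- if (!is.null(prim$attributes$COLOR_0)) {
      read_accessor(prim$attributes$COLOR_0)
    } else NULL
    idx <- read_accessor(prim$indices)
    list(name = nd$name,
         translation = if (is.null(nd$translation)) c(0, 0, 0) else unlist(nd$translation),
         vertices = verts,
         triangles = matrix(idx + 1L, ncol = 3L, byrow = TRUE),
         colors = cols)
  })
  list(asset_version = json$asset$version, glb_version = version, nodes = nodes)
}
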