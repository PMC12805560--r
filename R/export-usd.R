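# USDZ export. A USDZ package is an *uncompressed* zip whose first entry is
# a USD file and whose entry payloads sit on 64-byte boundaries; we write
# the USD layer as usda text, which is conformant and keeps the archive
# inspectable.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 7)
  trimws(out)
}

fmt_vec3 <- function(m) {
  paste0("(", fmt_num(m[, 1]), ", ", fmt_num(m[, 2]), ", ", fmt_num(m[, 3]), ")")
}

usda_text <- function(scene, options) {
  check_scene(scene)
  nodes <- scene_node_meshes(scene)
  prim_names <- sanitize_names(vapply(nodes, `[[`, character(1), "name"), usd = TRUE)

  blocks <- vapply(seq_along(nodes), function(k) {
    mesh <- nodes[[k]]$mesh
    tr <- nodes[[k]]$translation
    nt <- nrow(mesh$triangles)
    bb <- mesh_bounds(mesh)
    paste0(
      '    def Xform "', prim_names[k], '"\n    {\n',
      "        double3 xformOp:translate = (",
      fmt_num(tr[1]), ", ", fmt_num(tr[2]), ", ", fmt_num(tr[3]), ")\n",
      '        uniform token[] xformOpOrder = ["xformOp:translate"]\n\n',
      '        def Mesh "geom"\n        {\n',
      "            float3[] extent = [",
      paste(fmt_vec3(rbind(bb$min, bb$max)), collapse = ", "), "]\n",
      "            int[] faceVertexCounts = [",
      paste(rep("3", nt), collapse = ", "), "]\n",
      "            int[] faceVertexIndices = [",
      paste(as.vector(t(mesh$triangles)) - 1L, collapse = ", "), "]\n",
      "            point3f[] points = [",
      paste(fmt_vec3(mesh$vertices), collapse = ", "), "]\n",
      "            color3f[] primvars:displayColor = [",
      paste(fmt_vec3(mesh$colors), collapse = ", "), "] (\n",
      '                interpolation = "vertex"\n            )\n',
      '            uniform token subdivisionScheme = "none"\n',
      "        }\n    }\n"
    )
  }, character(1))

  paste0(
    "#usda 1.0\n(\n",
    '    defaultPrim = "Scene"\n',
    "    metersPerUnit = ", fmt_num(options$scale), "\n",
    '    upAxis = "Y"\n)\n\n',
    'def Xform "Scene"\n{\n',
    paste(blocks, collapse = "\n"),
    "}\n"
  )
}

#' Write a scene as a USDZ package
#'
#' USDZ is the AR asset package consumed natively by Apple's AR toolchain:
#' a zip archive with every entry stored uncompressed and payloads aligned
#' to 64 bytes, led by a USD file. The scene is written as a usda text
#' layer with one named mesh prim per scene node, per-vertex display
#' colors, Y-up, and `metersPerUnit` set from `options$scale`.
#'
#' @inheritParams write_glb
#' @return `path`, invisibly.
#' @export
write_usdz <- function(scene, path, options = export_options()) {
  raw <- usdz_raw(scene, options)
  writeBin(raw, path)
  invisible(path)
}

usdz_raw <- function(scene, options) {
  usda <- charToRaw(usda_text(scene, options))
  zip_build(list("model.usda" = usda), align = 64L)
}

#' Write a batch of scenes as a zip of USDZ files
#'
#' The download option for batches: a standard zip archive containing one
#' `.usdz` per scene. File names are the sanitized scene names; duplicates
#' get `_2`, `_3`, ... suffixes so nothing is overwritten.
#'
#' @param scenes List of `(name, scene)` pairs: each element a list with
#'   `name` (string) and `scene` (a `scene`).
#' @param path Output `.zip` path.
#' @param options An [export_options()] list.
#' @return `path`, invisibly.
#' @export
write_usdz_zip <- function(scenes, path, options = export_options()) {
  if (length(scenes) == 0L) {
    abort_mf("molforge_empty_scene", "no scenes to package")
  }
  names_in <- vapply(scenes, `[[`, character(1), "name")
  entry_names <- paste0(sanitize_names(names_in), ".usdz")
  entries <- lapply(scenes, function(s) usdz_raw(s$scene, options))
  names(entries) <- entry_names
  writeBin(zip_build(entries, align = NULL), path)
  invisible(path)
}
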