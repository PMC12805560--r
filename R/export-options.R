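#' Export options
#'
#' Shared settings for all exporters. Scene geometry is modeled in
#' Angstrom; `scale` converts to the meters that glTF and USD stages use.
#' The default of 0.02 m per Angstrom makes a cyclohexane model roughly
#' 10 cm across — tabletop size in AR. All exports are Y-up and
#' right-handed.
#'
#' @param scale Meters per Angstrom, `> 0`.
#' @param png_size Integer `(width, height)` in pixels for [render_png()],
#'   both `>= 16`.
#' @param camera Numeric `(azimuth_deg, elevation_deg, fit_margin)` for the
#'   renderer: the camera orbits the scene center at the given angles and
#'   backs off until the scene's bounding sphere fits with the margin.
#' @return An `export_options` list.
#' @export
export_options <- function(scale = 0.02, png_size = c(512L, 512L),
                           camera = c(azimuth = 25, elevation = 15, margin = 1.15)) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    abort_mf("molforge_bad_param", "scale must be a positive number")
  }
  if (length(png_size) != 2L || any(png_size < 16)) {
    abort_mf("molforge_bad_param", "png_size must be two values >= 16")
  }
  if (length(camera) != 3L || !is.numeric(camera)) {
    abort_mf("molforge_bad_param", "camera must be (azimuth, elevation, margin)")
  }
  list(scale = scale, png_size = as.integer(png_size),
       camera = unname(camera), up_axis = "Y")
}

check_scene <- function(scene) {
  if (!inherits(scene, "scene") || length(scene$nodes) == 0L) {
    abort_mf("molforge_empty_scene", "cannot export an empty scene")
  }
  invisible(scene)
}

# Identifier-safe names for file entries and USD prims, unique within a set.
sanitize_names <- function(names, usd = FALSE) {
  out <- gsub("[^A-Za-z0-9._-]", "_", names)
  if (usd) {
    out <- gsub("[^A-Za-z0-9_]", "_", out)
    bad_start <- grepl("^[0-9_]", out) | !nzchar(out)
    out[bad_start] <- paste0("m_", out[bad_start])
  }
  out[!nzchar(out)] <- "model"
  # deduplicate with _2, _3, ...
  counts <- table(out)
  if (any(counts > 1)) {
    seen <- new.env(parent = emptyenv())
    for (k in seq_along(out)) {
      nm <- out[k]
      prev <- if (is.null(seen[[nm]])) 0L else seen[[nm]]
      seen[[nm]] <- prev + 1L
      if (prev > 0L) out[k] <- paste0(nm, "_", prev + 1L)
    }
  }
  out
}
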