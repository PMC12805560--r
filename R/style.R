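#' Construct a style set for a molecular representation
#'
#' A style set bundles everything the model builder needs: the representation
#' kind, the per-element color/radius table, atom and bond proportions, and
#' tessellation density. Defaults follow the conventions of physical molecule
#' kits and CPK coloring:
#'
#' * `building_kit` (the default representation): atom balls at
#'   `0.45 * 2 * covalent` radius joined by uniform light-gray sticks of
#'   radius 0.12 Angstrom — the look of a classroom construction kit.
#' * `ball_and_stick`: atoms at `0.25 * vdw` radius, element-colored bond
#'   halves of radius 0.10 Angstrom.
#' * `space_filling`: atoms at full van der Waals radius, no bond geometry.
#'
#' Double and triple bonds are drawn as 2 or 3 parallel sticks separated by
#' `multi_bond_offset` (0.20 Angstrom).
#'
#' @param kind One of `"building_kit"`, `"ball_and_stick"`,
#'   `"space_filling"`. Hyphenated aliases (`"building-kit"`, ...) are
#'   accepted.
#' @param atom_scale Atom radius multiplier in `(0, 1]`; `NULL` picks the
#'   kind's default.
#' @param bond_radius Stick radius in Angstrom.
#' @param bond_color RGB triple for building-kit sticks.
#' @param multi_bond_offset Spacing between parallel sticks of a multiple
#'   bond, Angstrom.
#' @param sphere_lat,sphere_lon,cyl_segments Tessellation (latitude bands,
#'   longitude segments, cylinder segments).
#' @return A `style_set` object.
#' @examples
#' default_style("ball_and_stick")$atom_scale # 0.25
#' @export
default_style <- function(kind = c("building_kit", "ball_and_stick", "space_filling"),
                          atom_scale = NULL, bond_radius = NULL,
                          bond_color = c(0.75, 0.75, 0.75),
                          multi_bond_offset = 0.20,
                          sphere_lat = 12L, sphere_lon = 24L,
                          cyl_segments = 16L) {
  if (is.character(kind) && length(kind) == 1L) {
    kind <- gsub("-", "_", kind)
  }
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort_mf(
                     "molforge_style_error",
                     sprintf("unknown representation kind %s",
                             dQuote(paste(kind, collapse = "/"), q = FALSE))))
  if (is.null(atom_scale)) {
    atom_scale <- switch(kind, building_kit = 0.45, ball_and_stick = 0.25,
                         space_filling = 1.0)
  }
  if (is.null(bond_radius)) {
    bond_radius <- switch(kind, building_kit = 0.12, ball_and_stick = 0.10,
                          space_filling = 0.10)
  }
  if (atom_scale <= 0 || atom_scale > 1) {
    abort_mf("molforge_style_error", "atom_scale must be in (0, 1]")
  }
  if (bond_radius <= 0) {
    abort_mf("molforge_style_error", "bond_radius must be positive")
  }
  if (sphere_lat < 2 || sphere_lon < 3 || cyl_segments < 3) {
    abort_mf("molforge_style_error", "tessellation too coarse (lat >= 2, lon/segments >= 3)")
  }
  structure(list(
    kind = kind,
    element_table = element_table(),
    atom_scale = atom_scale,
    bond_radius = bond_radius,
    bond_color = bond_color,
    multi_bond_offset = multi_bond_offset,
    sphere_lat = as.integer(sphere_lat),
    sphere_lon = as.integer(sphere_lon),
    cyl_segments = as.integer(cyl_segments)
  ), class = "style_set")
}

#' Apply style overrides from a config file
#'
#' The config is plain `key = value` text, one setting per line; `#` starts
#' a comment. Recognized keys: `atom_scale`, `bond_radius`,
#' `multi_bond_offset`, `sphere_lat`, `sphere_lon`, `cyl_segments`
#' (numbers); `bond_color` (three comma-separated numbers in `[0, 1]`); and
#' per-element overrides `element.<symbol>.color` (RGB triple),
#' `element.<symbol>.covalent`, `element.<symbol>.vdw` (Angstrom).
#'
#' @param path Path to the config file.
#' @param style A `style_set` to override (default style of its kind).
#' @return The modified `style_set`.
#' @export
load_style_config <- function(path, style = default_style()) {
  if (!file.exists(path)) {
    abort_mf("molforge_file_not_found", sprintf("style config not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort_mf("molforge_style_error", sprintf("bad style config line: %s", ln))
    }
    key <- trimws(kv[[1]]); val <- trimws(kv[[2]])
    nums <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
    if (any(is.na(nums))) {
      abort_mf("molforge_style_error", sprintf("non-numeric style value: %s", ln))
    }
    if (grepl("^element\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3L) {
        abort_mf("molforge_style_error", sprintf("bad element override: %s", key))
      }
      el <- parts[[2]]; field <- parts[[3]]
      tab <- style$element_table
      i <- match(el, tab$element)
      if (is.na(i)) { # introduce a new element row based on the fallback
        tab <- rbind(tab, fallback_element(el))
        i <- nrow(tab)
      }
      if (field == "color" && length(nums) == 3L) {
        tab[i, c("r", "g", "b")] <- nums
      } else if (field %in% c("covalent", "vdw") && length(nums) == 1L) {
        tab[i, field] <- nums
      } else {
        abort_mf("molforge_style_error", sprintf("bad element override: %s", ln))
      }
      style$element_table <- tab
    } else if (key == "bond_color" && length(nums) == 3L) {
      style$bond_color <- nums
    } else if (key %in% c("atom_scale", "bond_radius", "multi_bond_offset",
                          "sphere_lat", "sphere_lon", "cyl_segments") &&
               length(nums) == 1L) {
      style[[key]] <- if (key %in% c("sphere_lat", "sphere_lon", "cyl_segments")) {
        as.integer(nums)
      } else nums
    } else {
      abort_mf("molforge_style_error", sprintf("unknown style key: %s", key))
    }
  }
  style
}

style_element <- function(style, element) {
  i <- match(element, style$element_table$element)
  if (is.na(i)) {
    warning(sprintf("element %s has no style entry; using fallback style", element),
            call. = FALSE)
    fallback_element(element)
  } else {
    style$element_table[i, , drop = FALSE]
  }
}
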