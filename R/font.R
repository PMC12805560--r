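# Built-in stroke font for scene labels: a 14-segment layout (plus a few
# hand-drawn polylines for punctuation) on a 0.6 x 1.0 glyph cell. Labels
# only need to identify a SMILES string at molecule scale, so fidelity is
# deliberately minimal; characters without a definition render as a box.

font_segments <- function() {
  list(
    a = list(c(0, 1), c(0.6, 1)),
    b = list(c(0.6, 1), c(0.6, 0.5)),
    c = list(c(0.6, 0.5), c(0.6, 0)),
    d = list(c(0, 0), c(0.6, 0)),
    e = list(c(0, 0.5), c(0, 0)),
    f = list(c(0, 1), c(0, 0.5)),
    g1 = list(c(0, 0.5), c(0.3, 0.5)),
    g2 = list(c(0.3, 0.5), c(0.6, 0.5)),
    h = list(c(0, 1), c(0.3, 0.5)),
    i = list(c(0.3, 1), c(0.3, 0.5)),
    j = list(c(0.6, 1), c(0.3, 0.5)),
    k = list(c(0, 0), c(0.3, 0.5)),
    l = list(c(0.3, 0), c(0.3, 0.5)),
    m = list(c(0.6, 0), c(0.3, 0.5))
  )
}

font_masks <- function() {
  list(
    "0" = c("a", "b", "c", "d", "e", "f"),
    "1" = c("b", "c"),
    "2" = c("a", "b", "g1", "g2", "e", "d"),
    "3" = c("a", "b", "c", "d", "g2"),
    "4" = c("f", "g1", "g2", "b", "c"),
    "5" = c("a", "f", "g1", "g2", "c", "d"),
    "6" = c("a", "f", "e", "d", "c", "g1", "g2"),
    "7" = c("a", "b", "c"),
    "8" = c("a", "b", "c", "d", "e", "f", "g1", "g2"),
    "9" = c("a", "b", "c", "d", "f", "g1", "g2"),
    A = c("a", "b", "c", "e", "f", "g1", "g2"),
    B = c("a", "b", "c", "d", "i", "l", "g2"),
    C = c("a", "d", "e", "f"),
    D = c("a", "b", "c", "d", "i", "l"),
    E = c("a", "d", "e", "f", "g1", "g2"),
    F = c("a", "e", "f", "g1"),
    G = c("a", "c", "d", "e", "f", "g2"),
    H = c("b", "c", "e", "f", "g1", "g2"),
    I = c("a", "d", "i", "l"),
    J = c("b", "c", "d", "e"),
    K = c("e", "f", "g1", "j", "m"),
    L = c("d", "e", "f"),
    M = c("b", "c", "e", "f", "h", "j"),
    N = c("b", "c", "e", "f", "h", "m"),
    O = c("a", "b", "c", "d", "e", "f"),
    P = c("a", "b", "e", "f", "g1", "g2"),
    Q = c("a", "b", "c", "d", "e", "f", "m"),
    R = c("a", "b", "e", "f", "g1", "g2", "m"),
    S = c("a", "c", "d", "f", "g1", "g2"),
    T = c("a", "i", "l"),
    U = c("b", "c", "d", "e", "f"),
    W = c("b", "c", "e", "f", "k", "m"),
    X = c("h", "j", "k", "m"),
    Y = c("h", "j", "l"),
    Z = c("a", "d", "j", "k")
  )
}

# Extra glyphs drawn as explicit polylines (list of lists of xy points).
font_polylines <- function() {
  list(
    V = list(list(c(0, 1), c(0.3, 0), c(0.6, 1))),
    "(" = list(list(c(0.45, 1), c(0.25, 0.7), c(0.25, 0.3), c(0.45, 0))),
    ")" = list(list(c(0.15, 1), c(0.35, 0.7), c(0.35, 0.3), c(0.15, 0))),
    "[" = list(list(c(0.45, 1), c(0.25, 1), c(0.25, 0), c(0.45, 0))),
    "]" = list(list(c(0.15, 1), c(0.35, 1), c(0.35, 0), c(0.15, 0))),
    "=" = list(list(c(0.05, 0.62), c(0.55, 0.62)), list(c(0.05, 0.38), c(0.55, 0.38))),
    "#" = list(list(c(0.15, 0.9), c(0.15, 0.1)), list(c(0.45, 0.9), c(0.45, 0.1)),
               list(c(0, 0.62), c(0.6, 0.62)), list(c(0, 0.38), c(0.6, 0.38))),
    "+" = list(list(c(0.3, 0.8), c(0.3, 0.2)), list(c(0.05, 0.5), c(0.55, 0.5))),
    "-" = list(list(c(0.1, 0.5), c(0.5, 0.5))),
    "." = list(list(c(0.25, 0), c(0.35, 0), c(0.35, 0.1), c(0.25, 0.1), c(0.25, 0))),
    "," = list(list(c(0.35, 0.1), c(0.2, -0.15))),
    "/" = list(list(c(0, 0), c(0.6, 1))),
    "\\" = list(list(c(0, 1), c(0.6, 0))),
    ":" = list(list(c(0.25, 0.2), c(0.35, 0.2)), list(c(0.25, 0.8), c(0.35, 0.8))),
    "@" = list(list(c(0.45, 0.35), c(0.45, 0.65), c(0.15, 0.65), c(0.15, 0.35),
                    c(0.45, 0.35), c(0.6, 0.2), c(0.6, 0.8), c(0, 0.8),
                    c(0, 0.2), c(0.6, 0.2))),
    "%" = list(list(c(0, 0), c(0.6, 1)), list(c(0, 1), c(0.15, 1), c(0.15, 0.85),
               c(0, 0.85), c(0, 1)), list(c(0.45, 0.15), c(0.6, 0.15),
               c(0.6, 0), c(0.45, 0), c(0.45, 0.15)))
  )
}

glyph_strokes <- function(ch) {
  segs <- font_segments()
  masks <- font_masks()
  polys <- font_polylines()
  up <- toupper(ch)
  if (!is.null(polys[[ch]])) {
    strokes <- list()
    for (pl in polys[[ch]]) {
      for (s in seq_len(length(pl) - 1L)) {
        strokes[[length(strokes) + 1L]] <- list(pl[[s]], pl[[s + 1L]])
      }
    }
    strokes
  } else if (!is.null(masks[[up]])) {
    segs[masks[[up]]]
  } else if (!is.null(polys[[up]])) {
    glyph_strokes(up)
  } else {
    # box glyph for anything undefined
    list(
      list(c(0, 0), c(0.6, 0)), list(c(0.6, 0), c(0.6, 1)),
      list(c(0.6, 1), c(0, 1)), list(c(0, 1), c(0, 0))
    )
  }
}

font_glyph_width <- function() 0.6
font_advance <- function() 0.8

#' Build a flat label mesh from text
#'
#' Draws the text with the built-in stroke font as thin quads in the XY
#' plane (facing +Z), for use as a scene label under each molecule. Any
#' character without a stroke definition renders as a box glyph. The mesh
#' is centered horizontally on x = 0 with its baseline at y = 0.
#'
#' @param text Non-empty label text (typically the SMILES string).
#' @param height Capital height in Angstrom.
#' @param color RGB triple.
#' @return A `triangle_mesh` of width
#'   `((nchar(text) - 1) * 0.8 + 0.6) * height`.
#' @export
make_label_mesh <- function(text, height = 1.0, color = c(0.15, 0.15, 0.15)) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort_mf("molforge_empty_input", "label text must be non-empty")
  }
  if (!is.numeric(height) || height <= 0) {
    abort_mf("molforge_bad_geometry_param", "label height must be positive")
  }
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  total_w <- ((n - 1) * font_advance() + font_glyph_width()) * height
  x0 <- -total_w / 2
  lw <- 0.08 * height # stroke half-profile
  parts <- list()
  for (ci in seq_along(chars)) {
    if (chars[ci] == " ") next
    off_x <- x0 + (ci - 1) * font_advance() * height
    for (st in glyph_strokes(chars[ci])) {
      p <- c(st[[1]] * height + c(off_x, 0))
      q <- c(st[[2]] * height + c(off_x, 0))
      d <- q - p
      len <- sqrt(sum(d^2))
      if (len < 1e-12) next
      perp <- c(-d[2], d[1]) / len * (lw / 2)
      v <- rbind(c(p + perp, 0), c(q + perp, 0), c(q - perp, 0), c(p - perp, 0))
      tr <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
      parts[[length(parts) + 1L]] <- new_mesh(
        v, tr, matrix(rep(color, each = 4), ncol = 3))
    }
  }
  merge_meshes(parts)
}
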