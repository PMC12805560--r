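#' Element property table
#'
#' Covalent radii (Cordero 2008), van der Waals radii (Bondi 1964), CPK-style
#' display colors and default valences for the elements the model builder
#' styles explicitly. Elements absent from the table render with a fallback
#' style (pink, generic radii) and never abort a build.
#'
#' @return A data frame with columns `element`, `valence`, `covalent`
#'   (Angstrom), `vdw` (Angstrom), `r`, `g`, `b` (color in `[0, 1]`).
#' @examples
#' element_table()[element_table()$element == "C", ]
#' @export
element_table <- function() {
  tab <- read.csv(
    textConnection(
      "element,valence,covalent,vdw,r,g,b
H,1,0.31,1.20,1.00,1.00,1.00
B,3,0.84,1.92,1.00,0.71,0.71
C,4,0.76,1.70,0.25,0.25,0.25
N,3,0.71,1.55,0.19,0.31,0.97
O,2,0.66,1.52,1.00,0.05,0.05
F,1,0.57,1.47,0.56,0.88,0.31
Si,4,1.11,2.10,0.94,0.78,0.63
P,3,1.07,1.80,1.00,0.50,0.00
S,2,1.05,1.80,1.00,1.00,0.19
Cl,1,1.02,1.75,0.12,0.94,0.12
Br,1,1.20,1.85,0.65,0.16,0.16
I,1,1.39,1.98,0.58,0.00,0.58"
    ),
    stringsAsFactors = FALSE
  )
  tab
}

# Fallback style for elements outside the table.
fallback_element <- function(element) {
  data.frame(
    element = element, valence = NA_real_, covalent = 0.75, vdw = 1.50,
    r = 1.00, g = 0.41, b = 0.71, stringsAsFactors = FALSE
  )
}

element_row <- function(element) {
  tab <- element_table()
  i <- match(element, tab$element)
  if (is.na(i)) fallback_element(element) else tab[i, , drop = FALSE]
}

# Default valence used for implicit-hydrogen counting; positive charge raises
# the valence of N/P-group donors, negative charge lowers it; carbocations
# lose a bond instead.
effective_valence <- function(element, charge = 0L) {
  v <- element_table()$valence[match(element, element_table()$element)]
  if (is.na(v)) return(NA_real_)
  if (element == "C" && charge > 0) v - charge else v + charge
}
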