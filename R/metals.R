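#' Default metal element set
#'
#' The 56 metal element symbols observed as ions across the wwPDB, used as
#' the default universe for metal-site detection. Supplied as configuration
#' rather than derived from a periodic-table taxonomy.
#'
#' @return Character vector of 56 element symbols in title case.
#' @export
default_metal_elements <- function() {
  c("Zn", "Mg", "Ca", "Fe", "Na", "Mn", "K",  "Ni", "Cu", "Co",
    "Cd", "Hg", "U",  "Pt", "Mo", "Al", "Be", "Ba", "Ru", "Sr",
    "V",  "Cs", "W",  "Yb", "Au", "Li", "Gd", "Pb", "Y",  "Tl",
    "Ir", "Rb", "Sm", "Ag", "Pr", "Eu", "Pd", "Os", "Re", "Rh",
    "Tb", "Ta", "Lu", "Ho", "La", "Cr", "Ga", "Sn", "Sb", "Ce",
    "Er", "Zr", "In", "Bi", "Hf", "Dy")
}

# normalize an element symbol to title case ("ZN" -> "Zn", " c" -> "C")
.normalize_element <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  ifelse(nchar(x) == 0, "",
         paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2))))
}
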