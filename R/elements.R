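#' @keywords internal
"_PACKAGE"

# Unit conversion constants, fixed package-wide.
HARTREE_TO_EV <- 27.211386
BOHR_TO_ANGSTROM <- 0.529177
HARTREE_TO_KCALMOL <- 627.5095
# Hessian units: Hartree/Bohr^2 -> kcal mol^-1 A^-2
HARTREE_BOHR2_TO_KCAL_A2 <- HARTREE_TO_KCALMOL / BOHR_TO_ANGSTROM^2

# Element table: standard atomic weights (amu) and van der Waals radii (A).
# Radii are the Bondi set where tabulated; metals without a Bondi entry carry
# ad-hoc values in the typical 2.0-2.5 A range used for heavy-ion silhouettes.
.element_table <- local({
  tab <- rbind(
    # symbol,  mass,      vdw
    c("H",  1.008,   1.20),
    c("He", 4.0026,  1.40),
    c("Li", 6.94,    1.82),
    c("Be", 9.0122,  1.53),
    c("B",  10.81,   1.92),
    c("C",  12.011,  1.70),
    c("N",  14.007,  1.55),
    c("O",  15.999,  1.52),
    c("F",  18.998,  1.47),
    c("Ne", 20.180,  1.54),
    c("Na", 22.990,  2.27),
    c("Mg", 24.305,  1.73),
    c("Al", 26.982,  1.84),
    c("Si", 28.085,  2.10),
    c("P",  30.974,  1.80),
    c("S",  32.06,   1.80),
    c("Cl", 35.45,   1.75),
    c("K",  39.098,  2.75),
    c("Ca", 40.078,  2.31),
    c("Sc", 44.956,  2.15),
    c("Ti", 47.867,  2.11),
    c("Mn", 54.938,  2.05),
    c("Fe", 55.845,  2.04),
    c("Co", 58.933,  2.00),
    c("Ni", 58.693,  1.63),
    c("Cu", 63.546,  1.40),
    c("Zn", 65.38,   1.39),
    c("Ga", 69.723,  1.87),
    c("Ge", 72.630,  2.11),
    c("As", 74.922,  1.85),
    c("Se", 78.971,  1.90),
    c("Br", 79.904,  1.85),
    c("Sr", 87.62,   2.49),
    c("Y",  88.906,  2.32),
    c("Zr", 91.224,  2.23),
    c("Tc", 98.0,    2.05),
    c("Ag", 107.87,  1.72),
    c("Cd", 112.41,  1.58),
    c("In", 114.82,  1.93),
    c("Sn", 118.71,  2.17),
    c("Sb", 121.76,  2.06),
    c("I",  126.90,  1.98),
    c("Cs", 132.91,  3.43),
    c("Ba", 137.33,  2.68),
    c("La", 138.91,  2.43),
    c("Gd", 157.25,  2.38),
    c("Tb", 158.93,  2.33),
    c("Ho", 164.93,  2.33),
    c("Yb", 173.05,  2.26),
    c("Lu", 174.97,  2.24),
    c("Re", 186.21,  2.05),
    c("Au", 196.97,  1.66),
    c("Hg", 200.59,  1.55),
    c("Tl", 204.38,  1.96),
    c("Pb", 207.2,   2.02),
    c("Bi", 208.98,  2.07),
    c("At", 210.0,   2.02),
    c("Ra", 226.0,   2.83),
    c("Ac", 227.0,   2.47),
    c("Th", 232.04,  2.45),
    c("U",  238.03,  1.86)
  )
  data.frame(
    symbol = tab[, 1],
    mass = as.numeric(tab[, 2]),
    vdw = as.numeric(tab[, 3]),
    stringsAsFactors = FALSE
  )
})

#' Look up element masses and van der Waals radii
#'
#' Returns tabulated standard atomic weights (amu) and van der Waals radii
#' (Angstrom) for chemical symbols. The embedded radius set is the Bondi
#' compilation, extended with values for metals that lack a Bondi entry.
#'
#' @param symbols character vector of element symbols (case-sensitive, e.g.
#'   `"Cu"`, `"O"`).
#' @return A data frame with columns `symbol`, `mass`, `vdw`, one row per
#'   input symbol.
#' @examples
#' element_properties(c("O", "H", "Cu"))
#' @export
element_properties <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  out <- .element_table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# normalize atom-name-ish strings ("CU", "o1") to tabulated symbols
normalize_element <- function(x) {
  x <- sub("[^A-Za-z].*$", "", trimws(x))
  two <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 2)))
  one <- toupper(substr(x, 1, 1))
  ifelse(two %in% .element_table$symbol, two, one)
}
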