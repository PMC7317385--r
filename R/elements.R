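#' @keywords internal
"_PACKAGE"

## Per-element reference data, H through Ar (Z = 1..18), with symbols up to Kr
## for geometry parsing. All radii stored in Angstrom and converted at use sites;
## everything else is in atomic units.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

## CODATA-ish standard atomic weights (used only for moments of inertia /
## rotational-constant deduplication).
ELEMENT_MASSES <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948,
  39.098, 40.078, 44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933,
  58.693, 63.546, 65.38, 69.723, 72.630, 74.922, 78.971, 79.904, 83.798
)

## Bondi van der Waals radii (Angstrom); Be/B/Al filled from later extensions
## of the Bondi set.
VDW_RADII_A <- c(
  H = 1.20, He = 1.40, Li = 1.81, Be = 1.53, B = 1.92, C = 1.70, N = 1.55,
  O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88
)

## Single-bond covalent radii (Angstrom), used by the CM5 correction.
COVALENT_RADII_A <- c(
  H = 0.32, He = 0.46, Li = 1.33, Be = 1.02, B = 0.85, C = 0.75, N = 0.71,
  O = 0.63, F = 0.64, Ne = 0.67, Na = 1.55, Mg = 1.39, Al = 1.26, Si = 1.16,
  P = 1.11, S = 1.03, Cl = 0.99, Ar = 0.96
)

## Bragg-Slater radii (Angstrom) used to scale Becke radial maps; noble gases
## filled with covalent values.
BRAGG_RADII_A <- c(
  H = 0.35, He = 0.31, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70, N = 0.65,
  O = 0.60, F = 0.50, Ne = 0.38, Na = 1.80, Mg = 1.50, Al = 1.25, Si = 1.10,
  P = 1.00, S = 1.00, Cl = 1.00, Ar = 0.71
)

## Slater-type model proatom exponents zeta0 (1/Bohr) for the bundled analytic
## proatom database: rho(r) = N * zeta^3/(8*pi) * exp(-zeta r). Values chosen
## as roughly twice the outermost-shell Slater-rule exponent so neutral-atom
## densities have realistic spatial extent.
SLATER_ZETA0 <- c(
  H = 2.0, He = 3.4, Li = 1.3, Be = 1.9, B = 2.4, C = 3.1, N = 3.7, O = 4.4,
  F = 5.1, Ne = 5.7, Na = 1.6, Mg = 2.0, Al = 2.3, Si = 2.7, P = 3.0,
  S = 3.4, Cl = 3.7, Ar = 4.0
)

#' Look up atomic numbers for element symbols
#'
#' @param symbols character vector of element symbols (case sensitive,
#'   e.g. "Na").
#' @return integer vector of atomic numbers.
#' @examples
#' element_number(c("H", "O"))
#' @export
element_number <- function(symbols) {
  z <- match(symbols, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' Look up element symbols for atomic numbers
#'
#' @param z integer vector of atomic numbers (1..36).
#' @return character vector of symbols.
#' @export
element_symbol <- function(z) {
  if (any(z < 1L | z > length(ELEMENT_SYMBOLS))) {
    stop("atomic number out of supported range 1..", length(ELEMENT_SYMBOLS))
  }
  ELEMENT_SYMBOLS[z]
}

element_mass <- function(symbols) {
  unname(ELEMENT_MASSES[element_number(symbols)])
}

lookup_radius <- function(symbols, table, what) {
  r <- table[symbols]
  if (anyNA(r)) {
    stop("no ", what, " radius for element(s): ",
         paste(unique(symbols[is.na(r)]), collapse = ", "),
         " (parameterized for H-Ar)")
  }
  unname(r)
}

## 1 Angstrom in Bohr.
ANGSTROM <- 1.8897261246
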