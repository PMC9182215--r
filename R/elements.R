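# Element data used across the package: symbol validation, van der Waals
# radii for Sterimol, covalent radii for bond perception.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

#' Van der Waals radius table (Bondi set)
#'
#' Bondi (1964) van der Waals radii in Angstrom, extended with the commonly
#' used value for boron, which Bondi did not tabulate. The table is the
#' default radius set for [sterimol()]; pass your own named vector to use a
#' different set.
#'
#' @return Named numeric vector of radii in Angstrom, names are element
#'   symbols.
#' @export
#' @examples
#' bondi_radii()[["H"]]
bondi_radii <- function() {
  c(
    H = 1.20, He = 1.40, Li = 1.82, B = 1.92, C = 1.70, N = 1.55,
    O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Al = 1.84,
    Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75,
    Ga = 1.87, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02,
    In = 1.93, Sn = 2.17, Te = 2.06, I = 1.98, Xe = 2.16
  )
}

#' Covalent radius table (Cordero set)
#'
#' Single-bond covalent radii in Angstrom used for distance-based bond
#' perception: two atoms are considered bonded when their separation is
#' below 1.3 times the sum of their covalent radii.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
covalent_radii <- function() {
  c(
    H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
    N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
    Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
    K = 2.03, Ca = 1.76, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20,
    Br = 1.20, Kr = 1.16, I = 1.39, Sn = 1.39, Te = 1.38
  )
}

is_element_symbol <- function(x) x %in% .element_symbols

#' Conversion constant from e-Angstrom to Debye
#'
#' Point-charge dipoles in this package carry units of elementary charge
#' times Angstrom; multiply by this constant to obtain Debye.
#'
#' @format A length-one numeric, 4.80320 D per e-Angstrom.
#' @export
EA_TO_DEBYE <- 4.80320
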