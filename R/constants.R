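#' Physical constants and unit conversions
#'
#' All internal arithmetic is in Hartree atomic units; energies are reported
#' in eV using the CODATA hartree-electronvolt relationship.
#' @name constants
NULL

#' Hartree to electronvolt conversion factor
#' @export
HARTREE_EV <- 27.211386245988

# 1 Angstrom in bohr
ANGSTROM_BOHR <- 1.8897259886

# supported elements
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

# Bragg-Slater radii (Angstrom), used only for Becke quadrature cell mapping
.bragg_radius <- c(
  H = 0.35, He = 0.31, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70, N = 0.65,
  O = 0.60, F = 0.50, Ne = 0.38, Na = 1.80, Mg = 1.50, Al = 1.25, Si = 1.10,
  P = 1.00, S = 1.00, Cl = 1.00, Ar = 0.71
)
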