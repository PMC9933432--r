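#' Physical constants and internal units
#'
#' Internal units throughout the package are Angstrom (length), picosecond
#' (time), atomic mass unit (mass), kcal/mol (energy), Kelvin (temperature)
#' and elementary charge (charge).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0019872041 kcal/(mol K).}
#'   \item{coulomb}{Coulomb prefactor, 332.0636 kcal A / (mol e^2).}
#'   \item{accel}{Conversion from (kcal/mol/A)/amu to A/ps^2, 418.4.}
#'   \item{kcal_per_amu_A2_ps2}{Kinetic-energy conversion, 1/418.4.}
#'   \item{amu_A3_to_g_cm3}{Density conversion from amu/A^3 to g/cm^3.}
#'   \item{bar_to_kcal_mol_A3}{Pressure conversion, 1 bar in kcal/(mol A^3).}
#' }
#' @export
UNITS <- list(
  kB = 0.0019872041,
  coulomb = 332.0636,
  accel = 418.4,
  kcal_per_amu_A2_ps2 = 1 / 418.4,
  amu_A3_to_g_cm3 = 1.66053907,
  bar_to_kcal_mol_A3 = 1.4393e-5
)
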