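## Physical constants and unit conversions used across the package.
## All internal mechanics are in GROMACS-style units: nm, kJ/mol, bar, e.

#' Physical constants used by recharge
#'
#' A named list of the unit conventions the package is built on:
#' \describe{
#'   \item{kB_kJ}{Boltzmann constant, kJ/mol/K.}
#'   \item{kB_kcal}{Boltzmann constant, kcal/mol/K.}
#'   \item{f_coulomb}{Coulomb prefactor \eqn{1/(4\pi\epsilon_0)} in
#'     kJ mol^-1 nm e^-2.}
#'   \item{bar_per_kJmolnm3}{Pressure conversion, 1 kJ/mol/nm^3 in bar.}
#'   \item{mNm_per_barnm}{Tension conversion, 1 bar nm in mN/m (exactly 0.1).}
#'   \item{debye_per_enm}{Dipole conversion, 1 e nm in Debye.}
#'   \item{water_molar_mass}{Molar mass of water, g/mol.}
#' }
#'
#' @export
recharge_constants <- list(
  kB_kJ            = 0.008314462618,
  kB_kcal          = 0.0019872041,
  f_coulomb        = 138.935458,
  bar_per_kJmolnm3 = 16.6054,
  mNm_per_barnm    = 0.1,
  debye_per_enm    = 48.03205,
  water_molar_mass = 18.015
)

#' Thermal energy kT
#'
#' @param temperature Temperature in K.
#' @param units `"kJ"` (kJ/mol) or `"kcal"` (kcal/mol).
#' @return kT in the requested units.
#' @examples
#' kT(298.15, "kcal") # ~0.5925 kcal/mol
#' @export
kT <- function(temperature, units = c("kJ", "kcal")) {
  units <- match.arg(units)
  stopifnot(is.numeric(temperature), temperature > 0)
  if (units == "kJ") recharge_constants$kB_kJ * temperature
  else recharge_constants$kB_kcal * temperature
}
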