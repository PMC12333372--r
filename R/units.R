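#' Physical constants and unit conversions
#'
#' The model layer works in eV and Angstrom throughout; free energies are
#' reported in kcal/mol.  Masses are in amu, time in fs, temperature in K.
#'
#' @name units
#' @keywords internal
NULL

## Boltzmann constant
KB_EV <- 8.617333262e-5      # eV / K
KB_KCAL <- 1.987204259e-3    # kcal / (mol K)

## energy conversion
EV_TO_KCAL <- 23.060548      # 1 eV in kcal/mol

## acceleration: force [eV/A] / mass [amu] -> [A / fs^2]
EV_A_AMU_ACC <- 9.648533212e-3

#' Thermal energy kT
#'
#' @param temperature temperature in K
#' @param units `"eV"` or `"kcal"` (kcal/mol)
#' @return kT in the requested units
#' @export
kT <- function(temperature, units = c("eV", "kcal")) {
  units <- match.arg(units)
  if (units == "eV") KB_EV * temperature else KB_KCAL * temperature
}
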