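#' Physical constants and thermal energy
#'
#' CODATA values used throughout. Energies are kJ/mol, lengths nm,
#' temperatures K.
#'
#' @name constants
#' @keywords internal
NULL

## Boltzmann constant, kJ/mol/K (k_B * N_A / 1000)
.kB_kJmol <- 1.380649e-23 * 6.02214076e23 / 1000

## Planck constant, J s
.h_Js <- 6.62607015e-34

## Boltzmann constant, J/K
.kB_JK <- 1.380649e-23

## elementary charge, C
.e_C <- 1.602176634e-19

#' Thermal energy k_B T in kJ/mol
#'
#' @param temperature temperature in K (default 310, physiological).
#' @return k_B T in kJ/mol (about 2.577 kJ/mol at 310 K).
#' @examples
#' kT(310)
#' @export
kT <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_kJmol * temperature
}
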