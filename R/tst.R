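#' Transition-state-theory conversions
#'
#' Conversions between unitary conductance, ion transition rates and
#' effective single-barrier heights: rate = g V / (q e) turns a conductance
#' into ions/s at a driving voltage, and the Eyring relation
#' k = (k_B T / h) exp(-dF / k_B T) links a rate to an effective free-energy
#' barrier. A 1 pS channel at 100 mV carries about 6.2e5 ions/s.
#'
#' @name tst
NULL

#' Convert unitary conductance to an ion transition rate
#'
#' @param conductance_pS conductance in pS.
#' @param voltage_mV driving voltage in mV (default 100).
#' @param charge_per_event elementary charges moved per transition (default
#'   1).
#' @return rate in 1/s.
#' @examples
#' conductance_to_rate(0.97, 100, 1)  # ~6.05e5 ions/s
#' @export
conductance_to_rate <- function(conductance_pS, voltage_mV = 100,
                                charge_per_event = 1) {
  stopifnot(conductance_pS > 0, voltage_mV > 0, charge_per_event > 0)
  (conductance_pS * 1e-12) * (voltage_mV * 1e-3) / (charge_per_event * .e_C)
}

#' Convert a rate to an effective TST barrier (Eyring)
#'
#' dF = k_B T ln(k_B T / (h k)). The inverse is [barrier_to_rate_tst()];
#' the two are exact round trips of each other.
#'
#' @param rate rate in 1/s.
#' @param temperature K. 298 K is the conventional choice for
#'   literature-derived estimates; 310 K matches physiological simulations.
#' @return barrier in kJ/mol.
#' @examples
#' rate_to_barrier_tst(6.05e5, 298)  # ~40 kJ/mol
#' @export
rate_to_barrier_tst <- function(rate, temperature = 298) {
  stopifnot(rate > 0, temperature > 0)
  prefactor <- .kB_JK * temperature / .h_Js
  if (rate > prefactor)
    warning("rate exceeds the TST prefactor k_B T / h: negative barrier",
            call. = FALSE)
  kT(temperature) * log(prefactor / rate)
}

#' @rdname rate_to_barrier_tst
#' @param barrier barrier in kJ/mol.
#' @export
barrier_to_rate_tst <- function(barrier, temperature = 298) {
  stopifnot(temperature > 0)
  (.kB_JK * temperature / .h_Js) * exp(-barrier / kT(temperature))
}
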