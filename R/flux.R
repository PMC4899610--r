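#' Calibrate the radical generation rate from a reference antioxidant run
#'
#' During the induction period of a potent reference antioxidant every
#' initiator-derived radical is assumed to end up trapped by the
#' antioxidant, so the total number of radicals generated over the lag
#' equals the stoichiometry times the antioxidant concentration:
#' \deqn{R_i = n \cdot [AH] / \tau}
#' With the chromanol reference (alpha-tocopherol, n = 2) at 1 uM and a
#' 170 min induction period this gives 11.8 nM/min.
#'
#' @param reference_conc Reference antioxidant concentration, M.
#' @param inhibition_duration Induction period (lag), minutes.
#' @param stoichiometry Radicals trapped per molecule (chromanol default 2).
#' @param reference Name of the reference antioxidant (metadata).
#' @return An object of class `radical_flux` with elements `Ri_M_min`,
#'   `Ri_nM_min`, `reference`, `reference_conc_M`, `reference_lag_min`,
#'   `stoichiometry`. Supports [tidy()].
#' @export
#' @examples
#' radical_flux(1e-6, 170, 2)$Ri_nM_min  # 11.8
radical_flux <- function(reference_conc, inhibition_duration,
                         stoichiometry = 2,
                         reference = "alpha-tocopherol") {
  stopifnot_scalar_number(reference_conc, "reference_conc", positive = TRUE)
  stopifnot_scalar_number(inhibition_duration, "inhibition_duration",
                          positive = TRUE)
  stopifnot_scalar_number(stoichiometry, "stoichiometry", positive = TRUE)
  Ri <- stoichiometry * reference_conc / inhibition_duration
  structure(
    list(
      Ri_M_min = Ri,
      Ri_nM_min = Ri * 1e9,
      reference = reference,
      reference_conc_M = reference_conc,
      reference_lag_min = inhibition_duration,
      stoichiometry = stoichiometry
    ),
    class = "radical_flux"
  )
}

#' @export
print.radical_flux <- function(x, ...) {
  cat(sprintf("<radical_flux> Ri = %.3g nM/min (from %g M %s, lag %g min, n = %g)\n",
              x$Ri_nM_min, x$reference_conc_M, x$reference,
              x$reference_lag_min, x$stoichiometry))
  invisible(x)
}

#' @rdname radical_flux
#' @param x A `radical_flux`.
#' @param ... Unused.
#' @export
tidy.radical_flux <- function(x, ...) {
  tibble(Ri_M_min = x$Ri_M_min, Ri_nM_min = x$Ri_nM_min,
         reference = x$reference, reference_conc_M = x$reference_conc_M,
         reference_lag_min = x$reference_lag_min,
         stoichiometry = x$stoichiometry)
}

as_Ri_M_min <- function(flux) {
  if (inherits(flux, "radical_flux")) return(flux$Ri_M_min)
  stopifnot_scalar_number(flux, "flux", positive = TRUE)
  flux
}

#' Chain propagation length
#'
#' Number of fatty-acid tails oxidized per initiating radical: the ratio
#' of the lipid oxidation rate to the radical generation rate. Values
#' above one indicate a propagating chain; values below one mean most
#' radicals are quenched before oxidizing a lipid.
#'
#' @param oxidation_rate Lipid oxidation rate, M/min (>= 0).
#' @param flux A [radical_flux()] or a plain Ri in M/min.
#' @return Dimensionless chain length.
#' @export
#' @examples
#' chain_propagation_length(334e-9, radical_flux(1e-6, 170, 2))  # ~28
chain_propagation_length <- function(oxidation_rate, flux) {
  Ri <- as_Ri_M_min(flux)
  if (!is.numeric(oxidation_rate) || any(!is.finite(oxidation_rate)) ||
      any(oxidation_rate < 0)) {
    abort("`oxidation_rate` must be finite and >= 0.",
          class = "clperox_domain_error")
  }
  oxidation_rate / Ri
}

#' Inhibition efficiency
#'
#' Ratio of the uninhibited to the inhibited steady oxidation rate; how
#' many fold an antioxidant slows lipid peroxidation.
#'
#' @param uninhibited_rate Uninhibited oxidation rate (same units as
#'   `inhibited_rate`).
#' @param inhibited_rate Inhibited oxidation rate (> 0).
#' @return Dimensionless efficiency. A non-positive inhibited rate is a
#'   domain error signalled with class `clperox_complete_inhibition`
#'   (oxidation fully suppressed; report a sentinel rather than a ratio).
#' @export
#' @examples
#' inhibition_efficiency(334, 3.28)  # ~102
inhibition_efficiency <- function(uninhibited_rate, inhibited_rate) {
  stopifnot_scalar_number(uninhibited_rate, "uninhibited_rate",
                          nonnegative = TRUE)
  if (!is.numeric(inhibited_rate) || !is.finite(inhibited_rate) ||
      inhibited_rate <= 0) {
    abort("Inhibited rate <= 0: complete inhibition, efficiency undefined.",
          class = c("clperox_complete_inhibition", "clperox_domain_error"))
  }
  uninhibited_rate / inhibited_rate
}

#' Radical-trapping stoichiometric factor
#'
#' Inverts the lag relation: the number of radicals each antioxidant
#' molecule trapped is the radical flux times the observed induction
#' period divided by the antioxidant concentration,
#' \eqn{n = R_i \tau / [AH]}. Chromanols approach 2; quinols fall short
#' because semiquinone autoxidation wastes part of the pool.
#'
#' @param flux A [radical_flux()] or Ri in M/min.
#' @param lag Observed induction period, minutes (>= 0).
#' @param antioxidant_conc Antioxidant concentration, M (> 0).
#' @return Dimensionless stoichiometric factor.
#' @export
#' @examples
#' stoichiometric_factor(radical_flux(1e-6, 170, 2), 170, 1e-6)  # 2
stoichiometric_factor <- function(flux, lag, antioxidant_conc) {
  Ri <- as_Ri_M_min(flux)
  stopifnot_scalar_number(antioxidant_conc, "antioxidant_conc", positive = TRUE)
  if (!is.numeric(lag) || !is.finite(lag) || lag < 0) {
    abort("`lag` must be finite and >= 0.", class = "clperox_domain_error")
  }
  Ri * lag / antioxidant_conc
}

#' Predicted induction period of an antioxidant
#'
#' The mirror image of [stoichiometric_factor()]: if each molecule traps
#' `stoichiometry` radicals and radicals arrive at a constant rate Ri, the
#' antioxidant is exhausted after \eqn{\tau = n [AH] / R_i} minutes.
#'
#' @param stoichiometry Radicals trapped per molecule (> 0).
#' @param antioxidant_conc Antioxidant concentration, M (>= 0).
#' @param Ri Radical generation rate, M/min (> 0), or a [radical_flux()].
#' @return Predicted lag in minutes.
#' @export
#' @examples
#' predicted_lag(2, 1e-6, radical_flux(1e-6, 170, 2))  # 170 min
predicted_lag <- function(stoichiometry, antioxidant_conc, Ri) {
  Ri <- as_Ri_M_min(Ri)
  stopifnot_scalar_number(stoichiometry, "stoichiometry", positive = TRUE)
  stopifnot_scalar_number(antioxidant_conc, "antioxidant_conc",
                          nonnegative = TRUE)
  stoichiometry * antioxidant_conc / Ri
}
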