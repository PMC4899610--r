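# Shared numeric and unit helpers.

# Molar absorptivity of conjugated dienes at 234 nm, M^-1 cm^-1.
EPSILON_DIENE <- 27400

# Instrument noise floor, absorbance units (UV setup at 230-300 nm).
NOISE_SD_AU <- 0.002

M_PER_MIN_TO_NM_PER_MIN <- 1e9
SECONDS_PER_MINUTE <- 60

#' Round a numeric vector half away from zero
#'
#' Base `round()` rounds half to even; reported tables in this field round
#' half up (e.g. an efficiency of 31.5 prints as 32).
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Reporting precision used for summary tables: rates to 3 significant
# figures, chain length and stoichiometric factor to 2, inhibition
# efficiency to the nearest integer.
round_rate <- function(x) signif(x, 3)
round_chain <- function(x) signif(x, 2)
round_stoich <- function(x) signif(x, 2)
round_efficiency <- function(x) round_half_up(x, 0)

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "clperox_domain_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x),
          class = "clperox_domain_error")
  }
  if (nonnegative && x < 0) {
    abort(sprintf("`%s` must be >= 0 (got %g).", name, x),
          class = "clperox_domain_error")
  }
  invisible(x)
}
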