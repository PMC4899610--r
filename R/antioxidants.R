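#' Describe a chain-breaking antioxidant
#'
#' Builds the record the spectral and simulation layers need for one
#' antioxidant: its structural class, the extinction coefficients used for
#' quantitation and kinetic monitoring, and the nominal radical-trapping
#' stoichiometry.
#'
#' Two wavelengths play different roles and are stored separately:
#' `epsilon_quinol_290` quantifies the reduced quinol stock at its 290 nm
#' absorbance maximum, while `epsilon_diff` scales the kinetic
#' "oxidized minus reduced" difference signal at `monitor_wavelength`
#' (281 nm for ubiquinones). When no dedicated difference coefficient is
#' known, the 290 nm value is used as a provisional default.
#'
#' @param name Antioxidant name (free text).
#' @param class One of `"ubiquinol"`, `"plastoquinol"`, `"chromanol"`.
#' @param epsilon_quinol_290 Molar absorptivity of the reduced form at
#'   290 nm, M^-1 cm^-1.
#' @param epsilon_diff Oxidized-minus-reduced difference molar
#'   absorptivity at `monitor_wavelength`, M^-1 cm^-1. Defaults to
#'   `epsilon_quinol_290`.
#' @param nominal_stoichiometry Radicals trapped per molecule in the ideal
#'   two-step quenching mechanism; defaults to 2 for every class
#'   (chromanols realise it, quinols fall short through semiquinone
#'   autoxidation).
#' @param monitor_wavelength Wavelength (nm) for kinetic redox monitoring.
#' @return A list of class `antioxidant_spec`.
#' @export
#' @examples
#' antioxidant_spec("Q10H2", "ubiquinol", epsilon_quinol_290 = 3940)
antioxidant_spec <- function(name,
                             class = c("ubiquinol", "plastoquinol", "chromanol"),
                             epsilon_quinol_290 = NA_real_,
                             epsilon_diff = epsilon_quinol_290,
                             nominal_stoichiometry = 2,
                             monitor_wavelength = 281) {
  class <- match.arg(class)
  if (!is.na(epsilon_quinol_290)) {
    stopifnot_scalar_number(epsilon_quinol_290, "epsilon_quinol_290",
                            positive = TRUE)
  }
  if (!is.na(epsilon_diff)) {
    stopifnot_scalar_number(epsilon_diff, "epsilon_diff", positive = TRUE)
  }
  stopifnot_scalar_number(nominal_stoichiometry, "nominal_stoichiometry",
                          positive = TRUE)
  structure(
    list(
      name = as.character(name),
      class = class,
      epsilon_quinol_290 = epsilon_quinol_290,
      epsilon_diff = epsilon_diff,
      nominal_stoichiometry = nominal_stoichiometry,
      monitor_wavelength = monitor_wavelength
    ),
    class = "antioxidant_spec"
  )
}

#' @export
print.antioxidant_spec <- function(x, ...) {
  cat(sprintf("<antioxidant_spec> %s (%s), eps290 = %s, eps_diff(%g nm) = %s, n_nominal = %g\n",
              x$name, x$class,
              format(x$epsilon_quinol_290), x$monitor_wavelength,
              format(x$epsilon_diff), x$nominal_stoichiometry))
  invisible(x)
}

#' Registry of the studied antioxidants
#'
#' Tabulates the quinol- and chromanol-type antioxidants used in
#' cardiolipin liposome oxidation assays together with their reduced-form
#' extinction coefficients at 290 nm (used to quantify borohydride-reduced
#' stocks) and the redox-monitoring wavelength. Tocopherol-type
#' (chromanol) compounds are not quantified via a 290 nm quinol band, so
#' their coefficient is `NA`.
#'
#' @return A tibble with one row per antioxidant: `name`, `class`,
#'   `epsilon_quinol_290` (M^-1 cm^-1), `nominal_stoichiometry`,
#'   `monitor_wavelength_nm`.
#' @export
#' @examples
#' antioxidant_registry()
antioxidant_registry <- function() {
  tibble(
    name = c("Q6H2", "Q10H2", "SkQ1H2", "decPQH2",
             "MitoQH2", "decUQH2", "alpha-tocopherol", "HPMC"),
    class = c("ubiquinol", "ubiquinol", "plastoquinol", "plastoquinol",
              "ubiquinol", "ubiquinol", "chromanol", "chromanol"),
    epsilon_quinol_290 = c(4890, 3940, 3540, 3540, 4140, 4140, NA, NA),
    nominal_stoichiometry = 2,
    monitor_wavelength_nm = c(281, 281, 281, 281, 281, 281, NA, NA)
  )
}

#' Look up an antioxidant_spec from the registry
#'
#' @param name Registry name (see [antioxidant_registry()]).
#' @return An [antioxidant_spec()].
#' @export
registry_spec <- function(name) {
  reg <- antioxidant_registry()
  row <- reg[reg$name == name, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown antioxidant `%s`; see antioxidant_registry().", name),
          class = "clperox_config_error")
  }
  antioxidant_spec(
    name = row$name, class = row$class,
    epsilon_quinol_290 = row$epsilon_quinol_290,
    nominal_stoichiometry = row$nominal_stoichiometry,
    monitor_wavelength = if (is.na(row$monitor_wavelength_nm)) 281
                         else row$monitor_wavelength_nm
  )
}

# Class-level kinetic defaults for the simulator. k_inh is the rate
# constant of peroxyl quenching by the reduced antioxidant; the chromanol
# value is set so that 1 uM traps about every second radical against
# 400 uM oxidizable tails (chain length ~ 1), as observed for
# alpha-tocopherol. k_auto is the semiquinone + O2 autoxidation rate
# constant; with oxygen clamped at saturation it sets the effective
# radical-trapping stoichiometry (chromanol ~ 2, ubiquinol ~ 1.8,
# plastoquinol ~ 1).
class_kinetics <- function(class) {
  switch(class,
    ubiquinol    = list(k_inh = 3e5, k_auto = 120),
    plastoquinol = list(k_inh = 3e5, k_auto = 3000),
    chromanol    = list(k_inh = 2.4e4, k_auto = 0),
    abort(sprintf("Unknown antioxidant class `%s`.", class),
          class = "clperox_config_error")
  )
}
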