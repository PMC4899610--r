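#' Convert absorbance to molar concentration (Beer-Lambert)
#'
#' @param a Absorbance (dimensionless), vectorised.
#' @param epsilon Molar absorptivity, M^-1 cm^-1.
#' @param path_length_cm Optical path length, cm (default 1).
#' @return Concentration in M.
#' @export
#' @examples
#' absorbance_to_concentration(0.04, 27400)  # ~1.5e-6 M conjugated dienes
absorbance_to_concentration <- function(a, epsilon, path_length_cm = 1) {
  stopifnot_scalar_number(epsilon, "epsilon", positive = TRUE)
  stopifnot_scalar_number(path_length_cm, "path_length_cm", positive = TRUE)
  a / (epsilon * path_length_cm)
}

#' Construct a kinetic trace
#'
#' A `kinetic_trace` is a tibble with columns `time_min`,
#' `concentration_M` and `species`, carrying the concentration-equivalent
#' noise floor as an attribute. Small negative concentrations arising from
#' instrument noise are retained (not clipped) so that rate fits stay
#' unbiased; values below minus three noise standard deviations trigger a
#' warning.
#'
#' @param time_min Time points, minutes.
#' @param concentration_M Concentrations, M.
#' @param species Species label.
#' @param noise_equivalent_M Noise floor expressed in M (one sd).
#' @return A tibble of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_min, concentration_M, species = "diene",
                          noise_equivalent_M = NOISE_SD_AU / EPSILON_DIENE) {
  if (length(time_min) != length(concentration_M)) {
    abort("`time_min` and `concentration_M` lengths differ.",
          class = "clperox_validation_error")
  }
  validate_monotone(time_min, "time_min")
  if (!all(is.finite(concentration_M))) {
    abort("Non-finite concentrations in kinetic trace.",
          class = "clperox_validation_error")
  }
  floor_M <- -3 * noise_equivalent_M
  if (any(concentration_M < floor_M)) {
    warn(sprintf(
      "%d concentration value(s) below -3 noise sd (%.3g M); retained unclipped.",
      sum(concentration_M < floor_M), floor_M
    ))
  }
  structure(
    tibble(time_min = as.numeric(time_min),
           concentration_M = as.numeric(concentration_M),
           species = species),
    class = c("kinetic_trace", class(tibble())),
    noise_equivalent_M = noise_equivalent_M
  )
}

#' Conjugated-diene kinetic trace from a spectral series
#'
#' Extracts the absorbance at 234 nm (nearest recorded column within 1 nm)
#' and converts it to the molar concentration of conjugated dienes via
#' Beer-Lambert using the diene molar absorptivity of 27400 M^-1 cm^-1.
#' The baseline policy removes the t = 0 offset that reference-cuvette
#' subtraction does not: either the absorbance at the first recorded time
#' point (default) or an explicit absorbance value.
#'
#' @param series A [as_spectral_series()] object.
#' @param wavelength Target wavelength, nm (default 234).
#' @param baseline `"first"` (default) or a numeric absorbance value.
#' @param epsilon Molar absorptivity, M^-1 cm^-1 (default 27400).
#' @return A [kinetic_trace()] labelled `"diene"`.
#' @export
diene_trace <- function(series, wavelength = 234, baseline = "first",
                        epsilon = EPSILON_DIENE) {
  wl <- match_wavelength(series, wavelength)
  l <- attr(series, "path_length_cm") %||% 1
  col <- dplyr::filter(as_tibble(series), .data$wavelength_nm == wl)
  col <- dplyr::arrange(col, .data$time_min)
  b <- if (identical(baseline, "first")) col$absorbance[1] else {
    stopifnot_scalar_number(baseline, "baseline")
    baseline
  }
  kinetic_trace(
    time_min = col$time_min,
    concentration_M = absorbance_to_concentration(col$absorbance - b, epsilon, l),
    species = "diene",
    noise_equivalent_M = NOISE_SD_AU / (epsilon * l)
  )
}

#' Oxidized-antioxidant kinetic trace from a spectral series
#'
#' Tracks the appearance of the oxidized form (quinone) of an antioxidant
#' through the "oxidized minus reduced" difference absorbance at the
#' spec's monitor wavelength, scaled by the difference extinction
#' coefficient. The returned trace carries a `plateau_time_min` attribute:
#' the first time from which the trace stays within noise of its final
#' value, i.e. the onset of antioxidant exhaustion.
#'
#' @param series A [as_spectral_series()] object.
#' @param spec An [antioxidant_spec()] with a finite `epsilon_diff`.
#' @param noise_sd_AU Instrument noise, absorbance units (default 0.002).
#'   The plateau tolerance is three noise sd in concentration units; for a
#'   noiseless series (`noise_sd_AU = 0`) it falls back to 0.5 % of the
#'   trace's dynamic range.
#' @param baseline `"first"` (default) or numeric absorbance.
#' @return A [kinetic_trace()] labelled `"<name>_oxidized"` with attribute
#'   `plateau_time_min`.
#' @export
antioxidant_trace <- function(series, spec, noise_sd_AU = NOISE_SD_AU,
                              baseline = "first") {
  if (!inherits(spec, "antioxidant_spec")) {
    abort("`spec` must be an antioxidant_spec.", class = "clperox_config_error")
  }
  if (is.null(spec$epsilon_diff) || is.na(spec$epsilon_diff)) {
    abort(sprintf("No difference extinction coefficient for `%s`.", spec$name),
          class = "clperox_config_error")
  }
  stopifnot_scalar_number(noise_sd_AU, "noise_sd_AU", nonnegative = TRUE)
  wl <- match_wavelength(series, spec$monitor_wavelength)
  l <- attr(series, "path_length_cm") %||% 1
  col <- dplyr::filter(as_tibble(series), .data$wavelength_nm == wl)
  col <- dplyr::arrange(col, .data$time_min)
  b <- if (identical(baseline, "first")) col$absorbance[1] else {
    stopifnot_scalar_number(baseline, "baseline")
    baseline
  }
  conc <- absorbance_to_concentration(col$absorbance - b, spec$epsilon_diff, l)
  noise_M <- noise_sd_AU / (spec$epsilon_diff * l)

  tol <- if (noise_sd_AU > 0) 3 * noise_M else 0.005 * diff(range(conc))
  final <- conc[length(conc)]
  within <- abs(conc - final) <= tol
  # first index from which every later point stays within tolerance
  ok_from <- rev(cumprod(rev(within))) == 1
  plateau_time <- col$time_min[which(ok_from)[1]]

  tr <- kinetic_trace(col$time_min, conc,
                      species = paste0(spec$name, "_oxidized"),
                      noise_equivalent_M = noise_M)
  attr(tr, "plateau_time_min") <- plateau_time
  tr
}

#' Locate isosbestic points between two spectra
#'
#' An isosbestic point is a wavelength where the oxidized and reduced
#' forms of a chromophore absorb equally, so that a kinetic signal there
#' is insensitive to the redox state of the antioxidant. Crossings of the
#' difference spectrum (oxidized minus reduced) are located by linear
#' interpolation between grid points where its sign changes.
#'
#' @param ox_spectrum,red_spectrum Data frames with columns
#'   `wavelength_nm` and `epsilon`, sampled on an identical grid.
#' @param window Optional numeric length-2 wavelength interval (nm) to
#'   search within.
#' @return Numeric vector of isosbestic wavelengths (nm). If the two
#'   spectra coincide everywhere the crossing is undefined; the window (or
#'   grid) endpoints are returned with attribute `degenerate = TRUE`.
#' @export
find_isosbestic <- function(ox_spectrum, red_spectrum, window = NULL) {
  ox <- as_tibble(ox_spectrum)
  red <- as_tibble(red_spectrum)
  for (nm in c("wavelength_nm", "epsilon")) {
    if (!nm %in% names(ox) || !nm %in% names(red)) {
      abort(sprintf("Spectra need columns `wavelength_nm` and `epsilon`."),
            class = "clperox_validation_error")
    }
  }
  ox <- dplyr::arrange(ox, .data$wavelength_nm)
  red <- dplyr::arrange(red, .data$wavelength_nm)
  if (!isTRUE(all.equal(ox$wavelength_nm, red$wavelength_nm))) {
    abort("Oxidized and reduced spectra are sampled on different grids.",
          class = "clperox_validation_error")
  }
  wl <- ox$wavelength_nm
  d <- ox$epsilon - red$epsilon
  if (!is.null(window)) {
    keep <- wl >= min(window) & wl <= max(window)
    wl <- wl[keep]
    d <- d[keep]
  }
  if (length(wl) < 2) {
    abort("Fewer than two grid points in the search window.",
          class = "clperox_validation_error")
  }
  if (all(d == 0)) {
    out <- range(wl)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  crossings <- wl[d == 0]
  flips <- which(d[-length(d)] * d[-1] < 0)
  for (i in flips) {
    # linear interpolation of the sign change between grid points
    lambda <- wl[i] - d[i] * (wl[i + 1] - wl[i]) / (d[i + 1] - d[i])
    crossings <- c(crossings, lambda)
  }
  sort(unique(crossings))
}
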