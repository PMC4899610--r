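#' Build an antioxidant-efficiency summary table
#'
#' Aggregates per-replicate oxidation rates and inhibition durations into
#' one row per antioxidant with the five derived columns of a standard
#' liposome-peroxidation report: mean oxidation rate (nM/min, +/- sample
#' sd), chain propagation length (rate / Ri), inhibition efficiency
#' (uninhibited rate / inhibited rate), inhibition duration (min, +/- sd)
#' and radical-trapping stoichiometric factor (Ri x duration / [AH]).
#'
#' @param runs A data frame with one row per replicate run and columns
#'   `antioxidant` (label; the uninhibited group is identified by
#'   `uninhibited_label`), `rate_M_min` (fitted oxidation rate),
#'   `duration_min` (inhibition duration; `NA` where not applicable or
#'   not determinable) and optionally `conc_M` (antioxidant
#'   concentration, needed for the stoichiometric factor).
#' @param flux A [radical_flux()] (or Ri in M/min) used for chain lengths
#'   and stoichiometric factors.
#' @param uninhibited_label Value of `antioxidant` marking the
#'   no-antioxidant control group (default `"pure CL"`).
#' @param round Apply the reporting precision (rates 3 significant
#'   figures, chain length and stoichiometry 2, efficiency nearest
#'   integer)? Default `TRUE`.
#' @return A tibble of class `peroxidation_metrics`, one row per group:
#'   `antioxidant`, `rate_nM_min`, `rate_sd_nM_min`, `chain_length`,
#'   `inhibition_efficiency`, `inhibition_duration_min`,
#'   `duration_sd_min`, `stoichiometric_factor`, `n_replicates`,
#'   `low_n`. For the uninhibited row efficiency, duration and
#'   stoichiometry are `NA` (not applicable). Complete inhibition
#'   (non-positive mean inhibited rate) reports an `Inf` efficiency
#'   sentinel.
#' @export
build_metrics_table <- function(runs, flux, uninhibited_label = "pure CL",
                                round = TRUE) {
  runs <- as_tibble(runs)
  needed <- c("antioxidant", "rate_M_min")
  if (!all(needed %in% names(runs))) {
    abort("`runs` needs columns `antioxidant` and `rate_M_min`.",
          class = "clperox_config_error")
  }
  if (!"duration_min" %in% names(runs)) runs$duration_min <- NA_real_
  if (!"conc_M" %in% names(runs)) runs$conc_M <- NA_real_
  if (!uninhibited_label %in% runs$antioxidant) {
    abort(sprintf("No uninhibited group `%s` in `runs`.", uninhibited_label),
          class = "clperox_config_error")
  }
  Ri <- as_Ri_M_min(flux)

  groups <- dplyr::group_by(runs, .data$antioxidant)
  agg <- dplyr::summarise(
    groups,
    rate_stats = list(replicate_stats(.data$rate_M_min)),
    dur_stats = list(if (all(is.na(.data$duration_min))) NULL
                     else replicate_stats(.data$duration_min)),
    conc_M = .data$conc_M[1],
    .groups = "drop"
  )

  uninhib <- agg$rate_stats[[which(agg$antioxidant == uninhibited_label)]]
  uninhibited_rate <- uninhib$mean

  rows <- purrr::pmap(agg, function(antioxidant, rate_stats, dur_stats, conc_M) {
    is_control <- antioxidant == uninhibited_label
    rate <- rate_stats$mean
    dur <- if (is.null(dur_stats)) NA_real_ else dur_stats$mean
    eff <- if (is_control) NA_real_ else {
      tryCatch(inhibition_efficiency(uninhibited_rate, rate),
               clperox_complete_inhibition = function(e) Inf)
    }
    stoich <- if (is_control || is.na(dur) || is.na(conc_M)) NA_real_
              else stoichiometric_factor(Ri, dur, conc_M)
    tibble(
      antioxidant = antioxidant,
      rate_nM_min = rate * 1e9,
      rate_sd_nM_min = rate_stats$sd * 1e9,
      chain_length = chain_propagation_length(max(rate, 0), Ri),
      inhibition_efficiency = eff,
      inhibition_duration_min = if (is_control) NA_real_ else dur,
      duration_sd_min = if (is_control || is.null(dur_stats)) NA_real_
                        else dur_stats$sd,
      stoichiometric_factor = stoich,
      n_replicates = rate_stats$n,
      low_n = rate_stats$low_n
    )
  })
  out <- dplyr::bind_rows(rows)
  # control first, then by descending efficiency (most protective first)
  out <- out[order(out$antioxidant != uninhibited_label,
                   -dplyr::coalesce(out$inhibition_efficiency, Inf)), ]

  if (round) {
    out <- dplyr::mutate(
      out,
      rate_nM_min = round_rate(.data$rate_nM_min),
      rate_sd_nM_min = round_rate(.data$rate_sd_nM_min),
      chain_length = round_chain(.data$chain_length),
      inhibition_efficiency = round_efficiency(.data$inhibition_efficiency),
      inhibition_duration_min = round_rate(.data$inhibition_duration_min),
      duration_sd_min = round_rate(.data$duration_sd_min),
      stoichiometric_factor = round_stoich(.data$stoichiometric_factor)
    )
  }
  structure(out,
            class = c("peroxidation_metrics", class(tibble())),
            Ri_M_min = Ri,
            uninhibited_label = uninhibited_label,
            uninhibited_rate_M_min = uninhibited_rate)
}

#' @export
print.peroxidation_metrics <- function(x, ...) {
  cat(sprintf("<peroxidation_metrics> Ri = %.3g nM/min, control `%s` at %.3g nM/min\n",
              attr(x, "Ri_M_min") * 1e9, attr(x, "uninhibited_label"),
              attr(x, "uninhibited_rate_M_min") * 1e9))
  NextMethod()
}

#' Write a metrics table as TSV
#'
#' @param x A `peroxidation_metrics` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
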