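#' Rate constants of the radical chain reaction
#'
#' Collects the mass-action rate constants of azo-initiator-driven lipid
#' peroxidation with quinol/chromanol inhibition. All bimolecular
#' constants are in M^-1 s^-1; the radical source is zero-order in
#' M/min (converted internally to seconds).
#'
#' @param Ri_eff Effective radical generation rate, M/min. Lumps
#'   initiator decomposition and cage escape; the default 11.8 nM/min is
#'   the value calibrated from a 1 uM chromanol reference run with a
#'   170 min induction period ([radical_flux()]).
#' @param k_p Chain propagation LOO. + LH, M^-1 s^-1 (default 60, the
#'   literature constant for bis-allylic hydrogen abstraction from
#'   linoleate).
#' @param k_inh Antioxidant + LOO. quenching, M^-1 s^-1 (default 3e5).
#' @param k_t Termination 2 LOO., M^-1 s^-1. `NULL` (default) means
#'   "calibrate at simulation time" so that the uninhibited quasi-steady
#'   oxidation rate matches `target_uninhibited_rate` under the
#'   simulation's lipid load; see [calibrate_kt()].
#' @param k_q Semiquinone (or tocopheroxyl) + LOO. quenching, M^-1 s^-1
#'   (default `k_inh`).
#' @param k_disp Semiquinone disproportionation 2 QH. -> Q + QH2,
#'   M^-1 s^-1 (default 1e8, diffusion-limited radical-radical).
#' @param k_auto Semiquinone + O2 autoxidation, M^-1 s^-1 (default 0,
#'   the chromanol case; see [class_kinetics] defaults in
#'   `antioxidant_registry()` for quinol classes).
#' @param target_uninhibited_rate Uninhibited oxidation rate (M/min) the
#'   k_t calibration should reproduce (default 330 nM/min).
#' @return A list of class `rate_constants`.
#' @export
#' @examples
#' k <- rate_constants()
#' k$k_inh / k$k_p  # 5000: quenching vs hydrogen abstraction
rate_constants <- function(Ri_eff = 11.8e-9, k_p = 60, k_inh = 3e5,
                           k_t = NULL, k_q = k_inh, k_disp = 1e8,
                           k_auto = 0,
                           target_uninhibited_rate = 330e-9) {
  for (nm in c("Ri_eff", "k_p", "k_inh", "k_q", "k_disp", "k_auto",
               "target_uninhibited_rate")) {
    stopifnot_scalar_number(get(nm), nm, nonnegative = TRUE)
  }
  if (!is.null(k_t)) stopifnot_scalar_number(k_t, "k_t", nonnegative = TRUE)
  structure(
    list(Ri_eff = Ri_eff, k_p = k_p, k_inh = k_inh, k_t = k_t,
         k_q = k_q, k_disp = k_disp, k_auto = k_auto,
         target_uninhibited_rate = target_uninhibited_rate),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(
    "<rate_constants> Ri_eff = %.3g nM/min, k_p = %g, k_inh = %g, k_t = %s, k_q = %g, k_disp = %g, k_auto = %g M^-1 s^-1\n",
    x$Ri_eff * 1e9, x$k_p, x$k_inh,
    if (is.null(x$k_t)) "calibrated" else format(x$k_t), x$k_q,
    x$k_disp, x$k_auto))
  invisible(x)
}

#' Calibrate the termination constant from the uninhibited steady rate
#'
#' In the termination-limited quasi-steady state the peroxyl pool obeys
#' \eqn{R_i = 2 k_t [LOO.]^2}, so the uninhibited oxidation rate is
#' \eqn{R_{ox} = k_p [LH] \sqrt{R_i / (2 k_t)}}. Inverting for k_t pins
#' the one constant the assay does not give directly to the observed
#' uninhibited rate (default 330 nM/min at 400 uM oxidizable tails).
#'
#' @param constants A [rate_constants()].
#' @param lh_M Oxidizable tail concentration, M.
#' @return The calibrated k_t in M^-1 s^-1.
#' @export
calibrate_kt <- function(constants, lh_M) {
  stopifnot_scalar_number(lh_M, "lh_M", positive = TRUE)
  Ri_s <- constants$Ri_eff / SECONDS_PER_MINUTE
  Rox_s <- constants$target_uninhibited_rate / SECONDS_PER_MINUTE
  loo_ss <- Rox_s / (constants$k_p * lh_M)
  Ri_s / (2 * loo_ss^2)
}

#' Configure a peroxidation simulation
#'
#' Default values reproduce the standard assay: 100 uM cardiolipin
#' (4 oxidizable linoleoyl tails each, hence 400 uM tails), 50 uM
#' azo initiator (bookkeeping only — the radical source is the constant
#' flux in [rate_constants()]), 40 degrees C, oxygen clamped at aqueous
#' saturation, instrument noise 0.002 absorbance units, spectra sampled
#' every 5 minutes.
#'
#' @param cl_M Cardiolipin concentration, M (default 100e-6).
#' @param tails_per_cl Oxidizable tails per lipid (default 4).
#' @param initiator_M Azo initiator concentration, M (metadata;
#'   default 50e-6).
#' @param antioxidant An [antioxidant_spec()] or `NULL` for an
#'   uninhibited run.
#' @param antioxidant_conc_M Antioxidant concentration, M.
#' @param addition_time_min When the antioxidant is added, minutes after
#'   initiation (0 = pre-incorporated; 30 is the delayed-delivery
#'   protocol).
#' @param duration_min Simulated duration, minutes.
#' @param dt_min Output time step, minutes (default 0.5; spectra are
#'   resampled to 5 min at synthesis time).
#' @param temperature_C Assay temperature (metadata, default 40).
#' @param O2_M Clamped dissolved oxygen concentration, M (default 2e-4,
#'   air-saturated buffer; oxygen is never depleted).
#' @param noise_sd_AU Instrument noise for synthetic spectra, absorbance
#'   units (default 0.002).
#' @param seed Random seed for synthetic noise.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(cl_M = 100e-6, tails_per_cl = 4,
                              initiator_M = 50e-6,
                              antioxidant = NULL,
                              antioxidant_conc_M = 0,
                              addition_time_min = 0,
                              duration_min = 300,
                              dt_min = 0.5,
                              temperature_C = 40,
                              O2_M = 2e-4,
                              noise_sd_AU = NOISE_SD_AU,
                              seed = NULL) {
  stopifnot_scalar_number(cl_M, "cl_M", nonnegative = TRUE)
  stopifnot_scalar_number(tails_per_cl, "tails_per_cl", positive = TRUE)
  stopifnot_scalar_number(antioxidant_conc_M, "antioxidant_conc_M",
                          nonnegative = TRUE)
  stopifnot_scalar_number(duration_min, "duration_min", positive = TRUE)
  stopifnot_scalar_number(dt_min, "dt_min", positive = TRUE)
  stopifnot_scalar_number(O2_M, "O2_M", nonnegative = TRUE)
  stopifnot_scalar_number(noise_sd_AU, "noise_sd_AU", nonnegative = TRUE)
  if (addition_time_min < 0 || addition_time_min >= duration_min) {
    abort("`addition_time_min` must lie within [0, duration).",
          class = "clperox_config_error")
  }
  if (!is.null(antioxidant) && !inherits(antioxidant, "antioxidant_spec")) {
    abort("`antioxidant` must be an antioxidant_spec or NULL.",
          class = "clperox_config_error")
  }
  structure(
    list(cl_M = cl_M, tails_per_cl = tails_per_cl,
         initiator_M = initiator_M,
         antioxidant = antioxidant,
         antioxidant_conc_M = antioxidant_conc_M,
         addition_time_min = addition_time_min,
         duration_min = duration_min, dt_min = dt_min,
         temperature_C = temperature_C, O2_M = O2_M,
         noise_sd_AU = noise_sd_AU, seed = seed),
    class = "simulation_config"
  )
}

# Right-hand side of the mass-action system, time in seconds.
# States (M): LH, LOO, diene (cumulative LOOH), QH2, QHs (semiquinone),
# Q, quenched (cumulative LOO.-consuming antioxidant flux).
perox_rhs <- function(t, y, p) {
  with(as.list(c(y, p)), {
    quench1 <- k_inh * QH2 * LOO      # QH2  + LOO. -> QH. + LOOH
    quench2 <- k_q * QHs * LOO        # QH.  + LOO. -> Q   + LOOH
    disp <- k_disp * QHs^2            # 2 QH.       -> Q   + QH2
    auto <- k_auto * O2 * QHs         # QH.  + O2   -> Q   + superoxide
    prop <- k_p * LOO * LH            # LOO. + LH   -> LOOH + L. (-> LOO.)
    list(c(
      LH = -prop,
      LOO = Ri_s - 2 * k_t * LOO^2 - quench1 - quench2,
      diene = prop,
      QH2 = -quench1 + disp,
      QHs = quench1 - quench2 - 2 * disp - auto,
      Q = quench2 + disp + auto,
      quenched = quench1 + quench2
    ))
  })
}

#' Simulate azo-initiator-driven lipid peroxidation
#'
#' Numerically integrates the mass-action radical chain: a constant
#' zero-order peroxyl radical source (initiator decomposition with
#' instantaneous L. -> LOO. oxygen addition), chain propagation on the
#' oxidizable tail pool, bimolecular termination, and — when an
#' antioxidant is present — quenching by the reduced antioxidant,
#' quenching by its one-electron-oxidized radical, semiquinone
#' disproportionation and semiquinone autoxidation by clamped oxygen.
#' Delayed antioxidant delivery is modelled as a discontinuous state
#' update at the addition time with an integrator restart.
#'
#' @param config A [simulation_config()].
#' @param constants A [rate_constants()]; a `NULL` `k_t` is calibrated to
#'   the configured uninhibited rate via [calibrate_kt()] and recorded in
#'   the result.
#' @param rtol,atol Integrator tolerances (stiff solver; radical species
#'   sit many orders of magnitude below the lipid pool).
#' @return An object of class `peroxidation_sim`: `trajectories` (tibble
#'   with `time_min` and species columns in M), `config`, `constants`
#'   (with the calibrated `k_t` filled in). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
#' @examples
#' sim <- simulate_peroxidation(simulation_config(duration_min = 60))
#' glance(sim)
simulate_peroxidation <- function(config, constants = rate_constants(),
                                  rtol = 1e-8, atol = 1e-15) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config.",
          class = "clperox_config_error")
  }
  lh0 <- config$cl_M * config$tails_per_cl
  if (is.null(constants$k_t)) {
    constants$k_t <- calibrate_kt(constants, lh0)
    attr(constants, "k_t_calibrated") <- TRUE
  }
  p <- c(Ri_s = constants$Ri_eff / SECONDS_PER_MINUTE,
         k_p = constants$k_p, k_inh = constants$k_inh,
         k_t = constants$k_t, k_q = constants$k_q,
         k_disp = constants$k_disp, k_auto = constants$k_auto,
         O2 = config$O2_M)

  times_min <- seq(0, config$duration_min, by = config$dt_min)
  t_add <- config$addition_time_min
  aox0 <- if (is.null(config$antioxidant)) 0 else config$antioxidant_conc_M

  y0 <- c(LH = lh0, LOO = 0, diene = 0,
          QH2 = if (t_add == 0) aox0 else 0,
          QHs = 0, Q = 0, quenched = 0)

  run_ode <- function(y, tmin) {
    out <- deSolve::lsoda(y, tmin * SECONDS_PER_MINUTE, perox_rhs, p,
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      abort("Stiff integration failed; try tighter tolerances.",
            class = "clperox_integrator_error")
    }
    out
  }

  if (aox0 > 0 && t_add > 0) {
    pre_times <- unique(c(times_min[times_min <= t_add], t_add))
    out1 <- run_ode(y0, pre_times)
    y1 <- out1[nrow(out1), -1]
    y1[["QH2"]] <- y1[["QH2"]] + aox0
    post_times <- unique(c(t_add, times_min[times_min >= t_add]))
    out2 <- run_ode(y1, post_times)
    keep1 <- out1[out1[, "time"] %in% (times_min * SECONDS_PER_MINUTE), ,
                  drop = FALSE]
    keep2 <- out2[out2[, "time"] %in% (times_min * SECONDS_PER_MINUTE) &
                    out2[, "time"] > t_add * SECONDS_PER_MINUTE, ,
                  drop = FALSE]
    out <- rbind(keep1, keep2)
  } else {
    out <- run_ode(y0, times_min)
  }

  traj <- as_tibble(as.data.frame(out))
  names(traj)[1] <- "time_min"
  traj$time_min <- traj$time_min / SECONDS_PER_MINUTE

  # tiny integrator undershoots are zeroed; anything larger is a failure
  species <- setdiff(names(traj), "time_min")
  neg_floor <- -1e-10
  for (s in species) {
    v <- traj[[s]]
    if (any(v < neg_floor)) {
      abort(sprintf("Negative `%s` beyond tolerance: stiffness problem; tighten tolerances.", s),
            class = "clperox_integrator_error")
    }
    traj[[s]] <- pmax(v, 0)
  }

  structure(
    list(trajectories = traj, config = config, constants = constants,
         aox_total_M = aox0),
    class = "peroxidation_sim"
  )
}

#' @export
print.peroxidation_sim <- function(x, ...) {
  tr <- x$trajectories
  cat(sprintf(
    "<peroxidation_sim> %g min (%d points); final diene %.3g uM; antioxidant %s\n",
    max(tr$time_min), nrow(tr), tail(tr$diene, 1) * 1e6,
    if (is.null(x$config$antioxidant)) "none"
    else sprintf("%s %.3g uM (added at %g min)", x$config$antioxidant$name,
                 x$config$antioxidant_conc_M * 1e6,
                 x$config$addition_time_min)))
  invisible(x)
}

#' @rdname simulate_peroxidation
#' @param x A `peroxidation_sim`.
#' @param ... Unused.
#' @export
tidy.peroxidation_sim <- function(x, ...) {
  tidyr::pivot_longer(x$trajectories, -"time_min",
                      names_to = "species", values_to = "concentration_M")
}

#' @rdname simulate_peroxidation
#' @export
glance.peroxidation_sim <- function(x, ...) {
  tr <- x$trajectories
  tibble(
    duration_min = max(tr$time_min),
    final_diene_M = tail(tr$diene, 1),
    final_QH2_M = tail(tr$QH2, 1),
    radicals_quenched_M = tail(tr$quenched, 1),
    k_t = x$constants$k_t,
    Ri_nM_min = x$constants$Ri_eff * 1e9
  )
}

#' Extract the conjugated-diene trace of a simulation
#'
#' @param sim A [simulate_peroxidation()] result.
#' @return A [kinetic_trace()] of the cumulative diene concentration.
#' @export
sim_diene_trace <- function(sim) {
  kinetic_trace(sim$trajectories$time_min, sim$trajectories$diene,
                species = "diene", noise_equivalent_M = 0)
}

#' Quasi-steady oxidation rate of a simulated run
#'
#' The chain-carrier (peroxyl) pool of an uninhibited run relaxes to its
#' quasi-steady level on the timescale \eqn{\nu / (k_p [LH])} (chain
#' length over the pseudo-first-order propagation rate), about 19 min at
#' default conditions, after which the lipid pool slowly depletes. The
#' quasi-steady rate is therefore read off as the maximum local slope of
#' the diene trajectory — attained right after the radical transient,
#' before depletion bends the curve down.
#'
#' @param sim A [simulate_peroxidation()] result.
#' @return Oxidation rate in M/min.
#' @export
sim_steady_rate <- function(sim) {
  tr <- sim$trajectories
  max(local_slopes(tr$time_min, tr$diene))
}

#' Effective radical-trapping stoichiometry of a simulated antioxidant
#'
#' Integrates the two peroxyl-consuming antioxidant fluxes (quenching by
#' the reduced form and by its radical) up to antioxidant exhaustion and
#' divides by the initial antioxidant concentration. Disproportionation,
#' which regenerates the quinol without consuming a peroxyl radical, is
#' deliberately not counted as quenching — it shows up indirectly by
#' extending the lag.
#'
#' @param constants A [rate_constants()].
#' @param config A [simulation_config()] with a positive antioxidant
#'   concentration.
#' @param exhaustion_frac QH2 fraction of the initial pool below which
#'   the antioxidant counts as exhausted (default 1e-3).
#' @return Dimensionless stoichiometry, or `NA` with attribute
#'   `status = "not exhausted"` when the antioxidant outlives the
#'   simulated duration.
#' @export
effective_stoichiometry <- function(constants, config,
                                    exhaustion_frac = 1e-3) {
  if (config$antioxidant_conc_M <= 0) {
    abort("Config has no antioxidant.", class = "clperox_config_error")
  }
  sim <- simulate_peroxidation(config, constants)
  tr <- sim$trajectories
  tr <- tr[tr$time_min >= config$addition_time_min, ]
  aox0 <- config$antioxidant_conc_M
  exhausted <- which(tr$QH2 <= exhaustion_frac * aox0)
  if (length(exhausted) == 0) {
    out <- NA_real_
    attr(out, "status") <- "not exhausted"
    return(out)
  }
  tr$quenched[exhausted[1]] / aox0
}

#' Aqueous-phase competition slowdown factor
#'
#' When an antioxidant is delivered in non-oxidizable carrier liposomes
#' it cannot reach the target lipid phase, but it can intercept
#' water-dissolved initiator radicals before they attack the lipid. With
#' interception probability
#' \eqn{f = k_{inh}[AH] / (k_{inh}[AH] + k_p[tails])}
#' the lipid oxidation slows by \eqn{1/(1-f)}. The chain-amplified
#' variant scales the propagation denominator by the chain length,
#' reflecting that each non-intercepted radical oxidizes a whole chain
#' of tails; both variants are exposed because neither is uniquely
#' forced by the competition argument alone.
#'
#' @param antiox_conc Antioxidant concentration in the aqueous-exposed
#'   carrier, M (>= 0).
#' @param tails_conc Oxidizable tail concentration of the target
#'   liposomes, M (>= 0).
#' @param constants A [rate_constants()] supplying `k_inh` and `k_p`.
#' @param chain_length Chain propagation length, used only by the
#'   chain-amplified variant (default 1).
#' @param variant `"direct"` (default) or `"chain-amplified"`.
#' @return Dimensionless slowdown factor (>= 1); `Inf` when interception
#'   is certain (`tails_conc = 0` with antioxidant present).
#' @export
#' @examples
#' competition_slowdown(1e-6, 400e-6, rate_constants())  # 13.5
competition_slowdown <- function(antiox_conc, tails_conc,
                                 constants = rate_constants(),
                                 chain_length = 1,
                                 variant = c("direct", "chain-amplified")) {
  variant <- match.arg(variant)
  stopifnot_scalar_number(antiox_conc, "antiox_conc", nonnegative = TRUE)
  stopifnot_scalar_number(tails_conc, "tails_conc", nonnegative = TRUE)
  stopifnot_scalar_number(chain_length, "chain_length", positive = TRUE)
  if (antiox_conc == 0) return(1)
  amp <- if (variant == "chain-amplified") chain_length else 1
  denom <- constants$k_p * tails_conc * amp
  if (denom == 0) return(Inf)
  f <- constants$k_inh * antiox_conc / (constants$k_inh * antiox_conc + denom)
  1 / (1 - f)
}
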