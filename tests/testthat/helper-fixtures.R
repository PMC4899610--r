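# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small complete spectral grid with a deterministic absorbance pattern
make_series <- function(times = c(0, 5, 10), wavelengths = c(230, 234, 281),
                        fill = function(t, w) 1e-3 * t + 1e-4 * (w - 230)) {
  grid <- expand.grid(time_min = times, wavelength_nm = wavelengths)
  grid$absorbance <- mapply(fill, grid$time_min, grid$wavelength_nm)
  as_spectral_series(grid)
}

# constant-absorbance series at a single diene channel
make_flat_234 <- function(a = 0.04, times = seq(0, 25, by = 5)) {
  make_series(times, c(234), fill = function(t, w) a)
}

# piecewise-linear diene trace: slope1 until t_break, slope2 after (M/min)
make_piecewise_trace <- function(slope1 = 3e-9, slope2 = 330e-9,
                                 t_break = 100, t_end = 200, dt = 5) {
  t <- seq(0, t_end, by = dt)
  conc <- ifelse(t <= t_break, slope1 * t,
                 slope1 * t_break + slope2 * (t - t_break))
  kinetic_trace(t, conc)
}

# noiseless uninhibited run and its quasi-steady rate (heavy-ish, cached)
pure_sim <- function() cached("pure_sim", {
  simulate_peroxidation(simulation_config(duration_min = 180,
                                          noise_sd_AU = 0))
})
uninhibited_rate <- function() cached("uninhibited_rate", {
  sim_steady_rate(pure_sim())
})

# generic 1 uM antioxidant run with ideal chromanol stoichiometry (n = 2)
chromanol_sim <- function() cached("chromanol_sim", {
  spec <- antioxidant_spec("toc-like", "chromanol", epsilon_diff = 4000)
  cfg <- simulation_config(antioxidant = spec, antioxidant_conc_M = 1e-6,
                           duration_min = 300, noise_sd_AU = 0)
  simulate_peroxidation(cfg, rate_constants(k_auto = 0))
})

# synthetic assay panel written once to a session-stable directory
panel_dir <- function() file.path(tempdir(), "clperox-panel")
panel <- function() cached("panel", {
  generate_fixture_panel(seed = 42, dir = panel_dir())
})
panel_study <- function() cached("panel_study", {
  m <- panel()$manifest
  cfg <- study_config(
    tibble::tibble(file = file.path(panel_dir(), m$file),
                   antioxidant = m$antioxidant, conc_M = m$conc_M),
    rate_window = c(m$rate_window_start_min[1], m$rate_window_end_min[1]),
    round = FALSE
  )
  run_full_pipeline(cfg)
})
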