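test_that("no radical source means no radicals and no dienes", {
  sim <- simulate_peroxidation(
    simulation_config(duration_min = 60, noise_sd_AU = 0),
    rate_constants(Ri_eff = 0, k_t = 1000))
  tr <- sim$trajectories
  expect_equal(max(tr$LOO), 0)
  expect_equal(max(tr$diene), 0)
  expect_equal(tr$LH, rep(4e-4, nrow(tr)))
})

test_that("calibrated termination reproduces the uninhibited steady rate", {
  sim <- pure_sim()
  k <- sim$constants
  expect_true(isTRUE(attr(k, "k_t_calibrated")))
  rate <- sim_steady_rate(sim)
  # quasi-steady closed form R_ox = k_p [LH] sqrt(Ri / (2 k_t))
  closed <- k$k_p * 4e-4 * sqrt((k$Ri_eff / 60) / (2 * k$k_t)) * 60
  expect_lt(abs(rate - 330e-9) / 330e-9, 0.05)
  expect_lt(abs(rate - closed) / closed, 0.05)
})

test_that("an ideal inhibitor suppresses oxidation until its analytic exhaustion time", {
  sim <- chromanol_sim()
  tr <- sim$trajectories
  # diene accumulation stays below 5 nM/min through the bulk of the lag
  # (the inhibited rate scales as 1/[QH2], so it climbs near exhaustion)
  lag_part <- tr[tr$time_min <= 120, ]
  slopes <- diff(lag_part$diene) / diff(lag_part$time_min)
  expect_lt(max(slopes), 5e-9)
  # QH2 exhaustion near 2 x 1 uM / 11.8 nM/min ~ 169 min
  t_exh <- tr$time_min[which(tr$QH2 <= 0.01 * 1e-6)[1]]
  expect_lt(abs(t_exh - 169.5) / 169.5, 0.10)
})

test_that("conservation and monotonicity hold across default scenarios", {
  spec <- registry_spec("Q10H2")
  scenarios <- list(
    pure = simulate_peroxidation(
      simulation_config(duration_min = 120, noise_sd_AU = 0)),
    incorporated = simulate_peroxidation(
      simulation_config(antioxidant = spec, antioxidant_conc_M = 1e-6,
                        duration_min = 250, noise_sd_AU = 0),
      rate_constants(k_auto = 120)),
    delayed = simulate_peroxidation(
      simulation_config(antioxidant = spec, antioxidant_conc_M = 1e-6,
                        addition_time_min = 30, duration_min = 250,
                        noise_sd_AU = 0),
      rate_constants(k_auto = 120))
  )
  for (nm in names(scenarios)) {
    tr <- scenarios[[nm]]$trajectories
    aox <- scenarios[[nm]]$aox_total_M
    t_add <- scenarios[[nm]]$config$addition_time_min
    post <- tr[tr$time_min > t_add, ]

    # lipid pool: LH + cumulative diene is conserved
    expect_equal(post$LH + post$diene, rep(4e-4, nrow(post)),
                 tolerance = 1e-6)
    # quinone ring pool: QH2 + QH. + Q equals the added antioxidant
    expect_equal(post$QH2 + post$QHs + post$Q, rep(aox, nrow(post)),
                 tolerance = 1e-6)
    # dienes never decrease; QH2 never increases after addition
    expect_true(all(diff(post$diene) >= -1e-15))
    expect_true(all(diff(post$QH2) <= 1e-15))
    expect_true(all(tr$LOO >= 0))
  }
  # delayed addition collapses the radical pool and the oxidation rate
  tr <- scenarios$delayed$trajectories
  s_pre <- (tr$diene[tr$time_min == 30] - tr$diene[tr$time_min == 25]) / 5
  s_post <- (tr$diene[tr$time_min == 45] - tr$diene[tr$time_min == 40]) / 5
  expect_lt(s_post, s_pre / 10)
})

test_that("the uninhibited rate follows the square-root law in Ri", {
  base <- simulate_peroxidation(
    simulation_config(duration_min = 120, noise_sd_AU = 0),
    rate_constants(k_t = 1872.4))
  quad <- simulate_peroxidation(
    simulation_config(duration_min = 120, noise_sd_AU = 0),
    rate_constants(Ri_eff = 4 * 11.8e-9, k_t = 1872.4))
  ratio <- sim_steady_rate(quad) / sim_steady_rate(base)
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("effective stoichiometry responds to semiquinone autoxidation", {
  spec <- antioxidant_spec("probe", "chromanol", epsilon_diff = 4000)
  cfg <- simulation_config(antioxidant = spec, antioxidant_conc_M = 1e-6,
                           duration_min = 300, noise_sd_AU = 0)
  # no autoxidation: both quenching steps count, n -> 2
  expect_equal(effective_stoichiometry(rate_constants(k_auto = 0), cfg), 2,
               tolerance = 0.05)
  # overwhelming autoxidation: every semiquinone lost to oxygen, n -> 1
  expect_equal(effective_stoichiometry(rate_constants(k_auto = 1e9), cfg), 1,
               tolerance = 0.05)
  # never exhausted within the run: sentinel
  cfg_big <- simulation_config(antioxidant = spec, antioxidant_conc_M = 1e-4,
                               duration_min = 100, noise_sd_AU = 0)
  n_big <- effective_stoichiometry(rate_constants(), cfg_big)
  expect_true(is.na(n_big))
  expect_equal(attr(n_big, "status"), "not exhausted")
})

test_that("intermediate autoxidation shortens the lag proportionally to n", {
  # k_auto chosen from the semiquinone branching ratio to give n ~ 1.2
  spec <- antioxidant_spec("probe", "chromanol", epsilon_diff = 4000)
  cfg <- simulation_config(antioxidant = spec, antioxidant_conc_M = 1e-6,
                           duration_min = 300, noise_sd_AU = 0)
  k12 <- rate_constants(k_auto = 1146)
  n12 <- effective_stoichiometry(k12, cfg)
  expect_equal(n12, 1.2, tolerance = 0.1)
  ur <- uninhibited_rate()
  lag12 <- inhibition_duration(
    sim_diene_trace(simulate_peroxidation(cfg, k12)), ur)$duration_min
  lag20 <- inhibition_duration(
    sim_diene_trace(chromanol_sim()), ur)$duration_min
  expect_equal(lag12 / lag20, 0.6, tolerance = 0.1)
})

test_that("aqueous competition slowdown follows the interception closed form", {
  k <- rate_constants()
  expect_equal(competition_slowdown(0, 400e-6, k), 1)
  # k_inh[AH] = k_p[tails]: interception probability 1/2, slowdown 2
  ah_eq <- k$k_p * 400e-6 / k$k_inh
  expect_equal(competition_slowdown(ah_eq, 400e-6, k), 2)
  expect_equal(competition_slowdown(1e-6, 400e-6, k), 13.5)
  expect_equal(competition_slowdown(1e-6, 400e-6, k, chain_length = 28,
                                    variant = "chain-amplified"),
               1 + 0.3 / (0.024 * 28))
  expect_equal(competition_slowdown(1e-6, 0, k), Inf)
})

test_that("deterministic trajectories agree with an exact stochastic oracle", {
  # reduced network at small copy numbers: constant radical source,
  # bimolecular quenching by a finite antioxidant pool, linear propagation
  a <- 1; c2 <- 0.002; c3 <- 0.5; qh2_0 <- 500; t_end <- 100
  set.seed(4242)
  ssa <- ssa_reduced_means(a, c2, c3, qh2_0, t_end, n_runs = 1000)
  ode <- ode_reduced_final(a, c2, c3, qh2_0, t_end)
  for (sp in c("QH2", "D")) {
    expect_lt(abs(ssa$mean[[sp]] - ode[[sp]]),
              5 * ssa$se[[sp]] + 0.005 * ode[[sp]])
  }
})
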