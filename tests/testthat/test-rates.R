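test_that("two-point rate fits reduce to the 25-minute difference quotient", {
  tr <- kinetic_trace(c(0, 25), c(0, 8.25e-6))
  fit <- fit_oxidation_rate(tr, c(0, 25))
  expect_equal(fit$rate_M_min, 3.3e-7)
  expect_equal(fit$n_points, 2L)
  expect_equal(fit$rms_M, 0)
})

test_that("OLS slope matches a closed-form oracle and degenerate cases", {
  expect_equal(fit_oxidation_rate(kinetic_trace(0:10, rep(2e-6, 11)),
                                  c(0, 10))$rate_M_min, 0)

  t <- seq(0, 95, by = 5)
  tr <- kinetic_trace(t, 1e-7 + 5e-9 * t)
  fit <- fit_oxidation_rate(tr, c(0, 95))
  # closed-form OLS on a noiseless line recovers the slope to 1e-15 relative
  expect_equal(fit$rate_M_min, 5e-9, tolerance = 1e-15)
  expect_equal(fit$n_points, 20L)

  expect_error(fit_oxidation_rate(tr, c(200, 300)),
               class = "clperox_insufficient_data")
})

test_that("OLS equals the difference quotient exactly on 2-point input", {
  set.seed(7)
  for (i in 1:20) {
    t1 <- runif(1, 0, 50)
    t <- c(t1, t1 + runif(1, 1, 50))
    c_ <- runif(2, 0, 1e-5)
    fit <- fit_oxidation_rate(kinetic_trace(t, c_), range(t))
    expect_equal(fit$rate_M_min, diff(c_) / diff(t), tolerance = 1e-12)
  }
})

test_that("replicate statistics use the sample standard deviation", {
  expect_equal(replicate_stats(c(5, 5, 5)),
               tibble::tibble(mean = 5, sd = 0, n = 3L, low_n = FALSE))
  expect_equal(replicate_stats(c(2, 4, 6))$sd, 2)
  one <- replicate_stats(42)
  expect_equal(one$sd, 0)
  expect_true(one$low_n)
  expect_true(replicate_stats(c(1, 2))$low_n)
  expect_error(replicate_stats(numeric(0)),
               class = "clperox_insufficient_data")
})

test_that("replicate mean of noisy simulated uninhibited rates brackets the truth", {
  m <- panel()$manifest
  pure <- m[m$antioxidant == "pure CL", ]
  rates <- vapply(pure$file, function(f) {
    tr <- diene_trace(read_spectral_series(file.path(panel_dir(), f)))
    fit_oxidation_rate(tr, c(pure$rate_window_start_min[1],
                             pure$rate_window_end_min[1]))$rate_M_min
  }, numeric(1))
  st <- replicate_stats(rates * 1e9)
  expect_equal(st$n, 5L)
  expect_gt(st$sd, 0)
  expect_lt(abs(st$mean - pure$true_rate_nM_min[1]), 2 * st$sd + 1e-9)
})

test_that("radical flux calibration reproduces the reference arithmetic", {
  fx <- radical_flux(1e-6, 170, 2)
  expect_equal(signif(fx$Ri_nM_min, 3), 11.8)
  expect_equal(fx$Ri_M_min, 2e-6 / 170)
  expect_equal(radical_flux(1e-6, 100, 1)$Ri_nM_min, 10)
  # linear in the reference concentration
  expect_equal(radical_flux(2e-6, 170, 2)$Ri_M_min,
               2 * radical_flux(1e-6, 170, 2)$Ri_M_min)
  expect_error(radical_flux(1e-6, 0, 2), class = "clperox_domain_error")
  expect_error(radical_flux(1e-6, -10, 2), class = "clperox_domain_error")
})

test_that("chain length, efficiency and stoichiometry reproduce the printed cells", {
  fx <- radical_flux(1e-6, 170, 2)

  expect_equal(signif(chain_propagation_length(334e-9, 11.8e-9), 3), 28.3)
  expect_equal(round(chain_propagation_length(334e-9, fx)), 28)
  expect_equal(chain_propagation_length(11.8e-9, 11.8e-9), 1)
  expect_equal(signif(chain_propagation_length(4.55e-9, 11.8e-9), 2), 0.39)
  expect_error(chain_propagation_length(-1e-9, fx),
               class = "clperox_domain_error")

  expect_equal(clperox:::round_efficiency(inhibition_efficiency(334, 3.28)), 102)
  expect_equal(inhibition_efficiency(7.7, 7.7), 1)
  expect_equal(clperox:::round_efficiency(inhibition_efficiency(334, 10.6)), 32)
  expect_error(inhibition_efficiency(334, 0),
               class = "clperox_complete_inhibition")

  expect_equal(stoichiometric_factor(fx, 170, 1e-6), 2)
  expect_equal(stoichiometric_factor(fx, 0, 1e-6), 0)
  expect_equal(signif(stoichiometric_factor(11.8e-9, 104, 1e-6), 3), 1.23)
  expect_error(stoichiometric_factor(fx, -5, 1e-6),
               class = "clperox_domain_error")
})

test_that("predicted lag inverts the stoichiometric relation", {
  expect_equal(predicted_lag(2, 1e-6, 11.8e-9), 2e-6 / 11.8e-9 / 1)
  expect_equal(round(predicted_lag(2, 1e-6, 11.8e-9)), 169)
  expect_equal(predicted_lag(2, 0, 11.8e-9), 0)
  expect_equal(signif(predicted_lag(1, 1e-6, 11.8e-9), 3), 84.7)
  expect_error(predicted_lag(2, 1e-6, 0), class = "clperox_domain_error")
})

test_that("derived ratios are invariant under a common concentration scale", {
  for (k in c(0.1, 3, 1e3)) {
    expect_equal(chain_propagation_length(k * 334e-9, k * 11.8e-9),
                 chain_propagation_length(334e-9, 11.8e-9))
    expect_equal(inhibition_efficiency(k * 334, k * 4.55),
                 inhibition_efficiency(334, 4.55))
    expect_equal(stoichiometric_factor(k * 11.8e-9, 104, k * 1e-6),
                 stoichiometric_factor(11.8e-9, 104, 1e-6))
  }
})
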