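test_that("Beer-Lambert conversion reproduces the worked diene example", {
  # A234 = 0.04 with eps = 27400 corresponds to ~1.5 uM of oxidized tails
  expect_equal(absorbance_to_concentration(0.04, 27400, 1), 0.04 / 27400)
  expect_equal(signif(absorbance_to_concentration(0.04, 27400, 1), 2), 1.5e-6)
  expect_equal(absorbance_to_concentration(0, 27400), 0)
  expect_equal(absorbance_to_concentration(0.274, 27400, 1), 1.00e-5)
  expect_error(absorbance_to_concentration(0.1, 0),
               class = "clperox_domain_error")
  expect_error(absorbance_to_concentration(0.1, -5),
               class = "clperox_domain_error")
})

test_that("Beer-Lambert conversion is linear in absorbance", {
  a <- c(0, 0.01, 0.2, 1.5)
  for (k in c(0, 0.5, 2, 10)) {
    expect_equal(absorbance_to_concentration(k * a, 27400),
                 k * absorbance_to_concentration(a, 27400))
  }
})

test_that("diene_trace applies the baseline policy correctly", {
  flat <- make_flat_234(0.04)
  expect_equal(diene_trace(flat)$concentration_M, rep(0, 6))
  expect_equal(diene_trace(flat, baseline = 0)$concentration_M,
               rep(0.04 / 27400, 6))

  # linear rise of 0.226 AU over 25 min against a zero baseline ends at 8.25 uM
  rising <- make_series(seq(0, 25, by = 5), 234,
                        fill = function(t, w) 0.226 * t / 25)
  tr <- diene_trace(rising, baseline = 0)
  expect_equal(tail(tr$concentration_M, 1), 0.226 / 27400, tolerance = 1e-12)
  expect_equal(signif(tail(tr$concentration_M, 1), 3), 8.25e-6)
})

test_that("first-point baseline makes the trace translation invariant", {
  base <- make_series(seq(0, 30, by = 5), 234,
                      fill = function(t, w) 0.001 * t)
  for (shift in c(-0.05, 0, 0.1, 0.7)) {
    shifted <- base
    shifted$absorbance <- shifted$absorbance + shift
    shifted <- as_spectral_series(shifted)
    expect_equal(diene_trace(shifted)$concentration_M,
                 diene_trace(base)$concentration_M)
  }
})

test_that("kinetic traces warn below minus three noise sd but keep values", {
  expect_warning(kinetic_trace(c(0, 5), c(0, -1e-6)), "noise sd")
  tr <- suppressWarnings(kinetic_trace(c(0, 5), c(0, -1e-6)))
  expect_equal(tr$concentration_M[2], -1e-6)
  # small negatives within the noise band pass silently
  expect_silent(kinetic_trace(c(0, 5), c(0, -1e-8)))
})

test_that("antioxidant_trace converts the monitor channel and finds the plateau", {
  spec <- registry_spec("Q10H2")

  zero <- make_series(seq(0, 50, by = 5), c(234, 281),
                      fill = function(t, w) 0)
  tr0 <- antioxidant_trace(zero, spec)
  expect_equal(tr0$concentration_M, rep(0, 11))
  expect_equal(attr(tr0, "plateau_time_min"), 0)

  step <- make_series(seq(0, 200, by = 5), c(234, 281),
                      fill = function(t, w) {
                        if (w != 281) 0 else 0.01 * pmin(t, 100) / 100
                      })
  trs <- antioxidant_trace(step, spec, noise_sd_AU = 0)
  expect_equal(attr(trs, "plateau_time_min"), 100)

  no_eps <- antioxidant_spec("bare", "chromanol")
  expect_error(antioxidant_trace(step, no_eps),
               class = "clperox_config_error")
})

test_that("simulated quinol oxidation plateaus when the antioxidant is exhausted", {
  # 1 uM, n = 2, Ri = 11.8 nM/min: exhaustion after ~170 min
  sim <- chromanol_sim()
  spec <- antioxidant_spec("toc-like", "chromanol", epsilon_diff = 4000)
  ss <- synthesize_absorbance(sim, spec = spec, noise_sd_AU = 0)
  tr <- antioxidant_trace(ss, spec, noise_sd_AU = 0)
  expect_lt(abs(attr(tr, "plateau_time_min") - 170) / 170, 0.10)
})

test_that("isosbestic points are located by sign-change interpolation", {
  grid <- 230:240
  lin_ox <- tibble::tibble(wavelength_nm = grid, epsilon = grid - 235)
  lin_red <- tibble::tibble(wavelength_nm = grid, epsilon = 0)
  expect_equal(find_isosbestic(lin_ox, lin_red), 235)

  # two Gaussian bands constructed to cross near 233.5
  g <- function(mu, s, amp) tibble::tibble(
    wavelength_nm = seq(228, 242, by = 0.5),
    epsilon = amp * exp(-(seq(228, 242, by = 0.5) - mu)^2 / (2 * s^2)))
  ox <- g(238, 4, 1)
  red <- g(229, 4, 1)
  # brute-force oracle on a 1000x finer grid
  fine <- seq(228, 242, by = 5e-4)
  dfine <- exp(-(fine - 238)^2 / 32) - exp(-(fine - 229)^2 / 32)
  oracle <- fine[which(diff(sign(dfine)) != 0)[1]]
  expect_equal(oracle, 233.5, tolerance = 1e-3)
  hit <- find_isosbestic(ox, red, window = c(230, 240))
  expect_equal(hit, oracle, tolerance = 0.5)

  same <- find_isosbestic(lin_red, lin_red)
  expect_true(isTRUE(attr(same, "degenerate")))
  expect_equal(as.numeric(same), c(230, 240))

  bad_grid <- tibble::tibble(wavelength_nm = grid + 0.1, epsilon = 0)
  expect_error(find_isosbestic(lin_ox, bad_grid),
               class = "clperox_validation_error")
})
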