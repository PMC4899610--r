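test_that("a table built from the published mean rates reproduces its derived columns", {
  ref <- reference_metrics()
  runs <- tibble::tibble(
    antioxidant = ref$antioxidant,
    rate_M_min = ref$rate_nM_min * 1e-9,
    duration_min = ref$inhibition_duration_min,
    conc_M = ref$conc_uM * 1e-6
  )
  fx <- radical_flux(1e-6, 170, 2)
  tab <- build_metrics_table(runs, fx)
  merged <- merge(tab, ref, by = "antioxidant", suffixes = c("", "_ref"))
  expect_equal(merged$chain_length, merged$chain_length_ref)
  inh <- merged[merged$antioxidant != "pure CL", ]
  expect_equal(inh$inhibition_efficiency, inh$inhibition_efficiency_ref)
  # uninhibited row carries the not-applicable sentinels
  ctl <- tab[tab$antioxidant == "pure CL", ]
  expect_true(is.na(ctl$inhibition_efficiency))
  expect_true(is.na(ctl$inhibition_duration_min))
  expect_true(is.na(ctl$stoichiometric_factor))
})

test_that("a single uninhibited group yields one row with rate / Ri", {
  runs <- tibble::tibble(antioxidant = "pure CL",
                         rate_M_min = c(330e-9, 340e-9, 320e-9))
  tab <- build_metrics_table(runs, 11.8e-9, round = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$chain_length, 330e-9 / 11.8e-9)
  expect_equal(tab$n_replicates, 3L)
})

test_that("a missing uninhibited group is a configuration error", {
  runs <- tibble::tibble(antioxidant = "Q10H2", rate_M_min = 4e-9)
  expect_error(build_metrics_table(runs, 11.8e-9),
               class = "clperox_config_error")
})

test_that("complete inhibition reports the Inf efficiency sentinel", {
  runs <- tibble::tibble(antioxidant = c("pure CL", "perfect"),
                         rate_M_min = c(330e-9, 0))
  tab <- build_metrics_table(runs, 11.8e-9, round = FALSE)
  expect_equal(tab$inhibition_efficiency[tab$antioxidant == "perfect"], Inf)
})

test_that("the consistency triangle holds on unrounded tables", {
  set.seed(31)
  labels <- c("pure CL", paste0("aox", 1:4))
  runs <- dplyr::bind_rows(lapply(labels, function(l) {
    base <- if (l == "pure CL") 330e-9 else runif(1, 2e-9, 30e-9)
    tibble::tibble(antioxidant = l,
                   rate_M_min = base * (1 + rnorm(3, sd = 0.02)),
                   duration_min = if (l == "pure CL") NA_real_
                                  else runif(3, 40, 180),
                   conc_M = 1e-6)
  }))
  Ri <- 11.8e-9
  tab <- build_metrics_table(runs, Ri, round = FALSE)
  ctl_rate <- attr(tab, "uninhibited_rate_M_min") * 1e9
  inh <- tab[tab$antioxidant != "pure CL", ]
  # efficiency x inhibited rate = uninhibited rate
  expect_equal(inh$inhibition_efficiency * inh$rate_nM_min,
               rep(ctl_rate, nrow(inh)))
  # chain length x Ri = inhibited rate
  expect_equal(inh$chain_length * Ri * 1e9, inh$rate_nM_min)
  # n = Ri x lag / [AH]
  expect_equal(inh$stoichiometric_factor,
               Ri * inh$inhibition_duration_min / 1e-6)
})

test_that("reported tables apply the documented rounding policy", {
  runs <- tibble::tibble(
    antioxidant = c(rep("pure CL", 2), rep("Q10H2", 2)),
    rate_M_min = c(3.337e-7, 3.341e-7, 4.551e-9, 4.549e-9),
    duration_min = c(NA, NA, 104.2, 103.8),
    conc_M = c(NA, NA, 1e-6, 1e-6)
  )
  tab <- build_metrics_table(runs, radical_flux(1e-6, 170, 2))
  q10 <- tab[tab$antioxidant == "Q10H2", ]
  expect_equal(q10$chain_length, 0.39)          # 2 significant figures
  expect_equal(q10$inhibition_efficiency, 73)   # nearest integer
  expect_equal(q10$stoichiometric_factor, 1.2)  # 2 significant figures
  expect_equal(tab$rate_nM_min[tab$antioxidant == "pure CL"], 334)
})
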