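# clperox

Kinetic analysis of cardiolipin (CL) liposome peroxidation and
antioxidant efficiency, for researchers running (or modelling)
azo-initiator-driven lipid oxidation assays followed by UV
spectrophotometry.

Cardiolipin's four polyunsaturated tails make it the most oxidizable
lipid of the mitochondrial membrane. In the standard assay, 100 µM CL
liposomes are oxidized at 40 °C by a constant flux of peroxyl radicals
from a thermally decomposing azo initiator, and spectra over 210–300 nm
are recorded every 5 min: conjugated dienes (one per oxidized tail,
ε ≈ 27400 M⁻¹cm⁻¹) grow at 234 nm, and quinol-type antioxidants are
followed through their "oxidized minus reduced" difference band near
281 nm.

`clperox` provides, in tidyverse style (tibbles in and out, `tidy()` /
`glance()` / `autoplot()` methods):

* **Spectral layer** — read/write CSV spectral time series (long or
  wide), Beer–Lambert conversion to molar traces (`diene_trace()`,
  `antioxidant_trace()`), isosbestic-point location.
* **Metrics layer** — the classical derived quantities of inhibited
  autoxidation:
  - radical flux calibration `Ri = n·[AH]/τ` (`radical_flux()`),
  - chain propagation length `ν = R_ox/Ri`,
  - inhibition efficiency `R_uninh/R_inh`,
  - induction period by a deterministic intersection-of-lines fit
    (`inhibition_duration()`),
  - radical-trapping stoichiometry `n = Ri·τ/[AH]`,
  - replicate aggregation into a publication-style table
    (`build_metrics_table()`).
* **Simulator** — a stiff mass-action model of the radical chain
  (constant initiation, propagation at k_p = 60 M⁻¹s⁻¹, calibrated
  termination, antioxidant inhibition at k_inh = 3×10⁵ M⁻¹s⁻¹,
  semiquinone quenching/disproportionation/autoxidation), used both for
  mechanistic questions (`effective_stoichiometry()`,
  `competition_slowdown()`) and as the synthetic-data generator
  (`synthesize_absorbance()`, `generate_fixture_panel()`).
* **Workbench** — `run_full_pipeline()` from a set of spectral CSVs to
  the metrics table, and `reproduce_reference_metrics()`, an executable
  cross-check of the published benchmark arithmetic.

## Worked example

Calibrate the radical flux from the chromanol reference run and derive
the uninhibited chain length:

```r
library(clperox)

flux <- radical_flux(reference_conc = 1e-6, inhibition_duration = 170,
                     stoichiometry = 2)
flux
#> <radical_flux> Ri = 11.8 nM/min (from 1e-06 M alpha-tocopherol, lag 170 min, n = 2)

chain_propagation_length(330e-9, flux)
#> [1] 28.05
```

So each initiator-derived radical oxidizes about 28 lipid tails in the
absence of an antioxidant. Recomputing every derivable cell of the
bundled benchmark table from its printed mean rates:

```r
rep <- reproduce_reference_metrics()
rep[, c("antioxidant", "chain_recomputed", "efficiency_recomputed")]
#>        antioxidant chain_recomputed efficiency_recomputed
#> 1          pure CL            28.00                    NA
#> 2          decPQH2             0.28                   102
#> 3           SkQ1H2             0.33                    86
#> 4          decUQH2             0.38                    74
#> 5          MitoQH2             0.57                    50
#> 6             Q6H2             0.34                    82
#> 7            Q10H2             0.39                    73
#> 8 alpha-tocopherol             0.90                    32
#> 9             HPMC             0.73                    39
all(rep$chain_ok); all(rep$efficiency_ok)
#> [1] TRUE
#> [1] TRUE
```

A chain length of 0.39 for ubiquinol-10 means a radical is ~3× more
likely to be quenched than to oxidize a tail; an efficiency of 102 for
decPQH₂ means oxidation runs 102-fold slower than uninhibited. End to
end on synthetic data:

```r
panel <- generate_fixture_panel(seed = 42, dir = "panel")
cfg <- study_config(
  tibble::tibble(file = file.path("panel", panel$manifest$file),
                 antioxidant = panel$manifest$antioxidant,
                 conc_M = panel$manifest$conc_M),
  rate_window = c(40, 70))
run_full_pipeline(cfg)$metrics
```

which recovers the uninhibited rate (~317 nM/min measured in the
post-transient window), a chain length of 28, and the configured lags
and stoichiometries of each antioxidant class.

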