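---
title: "Kinetics of cardiolipin peroxidation and antioxidant efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of cardiolipin peroxidation and antioxidant efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clperox)
```

## The assay and its observables

Cardiolipin (CL) from heart mitochondria carries four linoleoyl tails and
is therefore exceptionally prone to radical chain peroxidation. The
standard in vitro assay follows the process spectrophotometrically:
liposomes of ~100 µM CL are incubated at 40 °C, the chain is started with
a thermally decomposing azo initiator (~50 µM) that emits peroxyl
radicals at a constant rate, and UV spectra over 210–300 nm are recorded
every 5 minutes against a reference cuvette. Two channels carry the
kinetics:

* **234 nm** — conjugated dienes, the rearranged double-bond pair formed
  in every oxidized polyunsaturated tail (ε ≈ 27400 M⁻¹cm⁻¹). Their
  accumulation measures lipid oxidation.
* **~281 nm** — the "oxidized minus reduced" difference band of
  quinone-type antioxidants, which tracks antioxidant consumption.
  Usefully, the oxidized/reduced difference spectra have isosbestic
  points near 234 nm, so the diene channel is essentially insensitive to
  the antioxidant's redox state (`find_isosbestic()` checks this for a
  given pair of spectra).

`clperox` turns such absorbance records into molar kinetic traces
(`diene_trace()`, `antioxidant_trace()`, plain Beer–Lambert conversion,
no smoothing or unmixing), derives the standard performance metrics of
chain-breaking antioxidants, and contains a mass-action simulator of the
whole reaction system that doubles as the package's synthetic-data
generator.

## Derived metrics

With $R_{ox}$ the slope of the diene trace (M/min) and $R_i$ the radical
generation rate, the package computes, per antioxidant:

* **Radical flux calibration** (`radical_flux()`). During the induction
  period of a potent reference antioxidant every generated radical ends
  up trapped, so $R_i = n\,[AH]/\tau$. The chromanol reference
  (α-tocopherol, $n = 2$) at 1 µM with a 170 min lag gives
  $R_i = 11.8$ nM/min.
* **Chain propagation length** $\nu = R_{ox}/R_i$
  (`chain_propagation_length()`): tails oxidized per initiating radical.
  The uninhibited assay gives $330/11.8 \approx 28$; a good quinol
  suppresses it below 0.4.
* **Inhibition efficiency** $R_{ox}^{uninh}/R_{ox}^{inh}$
  (`inhibition_efficiency()`), with a "complete inhibition" sentinel
  when the inhibited rate is not positive.
* **Inhibition duration** (`inhibition_duration()`), the classical
  intersection-of-lines construction, made deterministic (next section).
* **Stoichiometric factor** $n = R_i \tau / [AH]$
  (`stoichiometric_factor()`): radicals trapped per molecule.

`build_metrics_table()` aggregates per-replicate fits into the
conventional report (mean ± sample sd; groups with fewer than three
replicates are flagged). Reporting precision is fixed once: rates to 3
significant figures, chain length and stoichiometry to 2, efficiency to
the nearest integer (half away from zero) — the precision at which such
tables are printed.

## Lag estimation: a deterministic construction

The induction period is usually described only as "the intersection of
the inhibited and uninhibited lines". That leaves three free choices,
which the package pins down:

1. **Plateau segment**: the longest contiguous run of points, starting
   at the antioxidant addition time, whose local slope (central
   differences) stays below 25 % of the uninhibited rate.
2. **Terminal segment**: the last 20 % of points, or the equally long
   contiguous window of maximal mean slope — but the steep window is
   used only when its fit residual is at least twofold lower. Residuals
   within a factor of two are statistically indistinguishable under
   instrument noise, and letting noise flip the choice made replicate
   estimates bimodal; preferring the settled tail keeps them
   reproducible.
3. **Sentinels**: if no plateau exists the lag is 0 (`"no_lag"`); if the
   terminal slope never reaches 25 % of the uninhibited rate the
   antioxidant is still active (`"ongoing"`, duration `NA` — never
   imputed; this is how variable-loss antioxidants such as HPMC are
   reported).

One bias is inherent and worth knowing: after the antioxidant is
exhausted, the peroxyl chain-carrier pool must rebuild before the trace
reaches its terminal slope. In the mass-action model that relaxation
time is $\nu/(k_p[LH]) \approx 19$ min at default conditions, and the
back-extrapolated intersection overshoots the analytic lag
$n[AH]/R_i$ by up to $\tau_{relax}\ln 2 \approx 13$ min. For lags of
150 min and longer this is within 10 %; for short lags it dominates.
The test suite asserts exactly this two-part statement rather than a
uniform relative bound.

## The mass-action model

`simulate_peroxidation()` integrates, in seconds and molar units,

| step | reaction | rate |
|---|---|---|
| initiation | initiator → LOO• | $R_i$ (zero order) |
| propagation | LOO• + LH → LOOH + L• (→ LOO•) | $k_p$ = 60 M⁻¹s⁻¹ |
| termination | 2 LOO• → non-radical | $2k_t[\mathrm{LOO}]^2$ |
| inhibition | QH₂ + LOO• → QH• + LOOH | $k_{inh}$ |
| radical quench | QH• + LOO• → Q + LOOH | $k_q = k_{inh}$ |
| disproportionation | 2 QH• → Q + QH₂ | $k_{disp}$ = 10⁸ M⁻¹s⁻¹ |
| autoxidation | QH• + O₂ → Q + O₂•⁻ | $k_{auto}$ (class-specific) |

Modelling choices, each encoded in `rate_constants()` /
`simulation_config()`:

* **Constant radical source.** Initiator decomposition at fixed
  temperature produces radicals at a constant rate; the effective flux
  `Ri_eff` (default 11.8 nM/min, the calibrated value) lumps
  decomposition and cage escape, since neither the decomposition
  constant nor the escape efficiency is separately observable in this
  assay.
* **Oxygen is clamped** at aqueous saturation (default 200 µM) and the
  L• + O₂ step is collapsed into instantaneous conversion, so every
  carbon radical is born a peroxyl radical. Each initiation or
  propagation event converts one LH into (eventually) one conjugated
  diene, so cumulative LOOH and dienes coincide.
* **Calibrated termination.** $k_t$ is not measurable here; it is fixed
  once, by `calibrate_kt()`, so that the quasi-steady uninhibited rate
  $R_{ox} = k_p[LH]\sqrt{R_i/2k_t}$ equals 330 nM/min at 400 µM
  oxidizable tails (giving $k_t \approx 1.9 \times 10^3$ M⁻¹s⁻¹), and
  recorded in every simulation result.
* **Quasi-steady rate read-out.** Because the chain-carrier pool relaxes
  over ~19 min, the first half hour of a simulated uninhibited run
  underestimates the steady rate; `sim_steady_rate()` reports the
  maximum local slope (reached right after the transient, before lipid
  depletion bends the curve), and the synthetic-panel protocol fits
  uninhibited rates in a 40–70 min window.
* **Stiff integration** with `deSolve::lsoda`, rtol 10⁻⁸ and atol
  10⁻¹⁵ M: radical species sit six and more orders of magnitude below
  the lipid pool. Sub-tolerance negative excursions are zeroed; larger
  ones raise an error rather than being silently clipped. Delayed
  antioxidant delivery is a discontinuous state update with an
  integrator restart.

### Class-specific stoichiometry via the semiquinone branching ratio

Ideally one antioxidant molecule quenches two radicals (reduced form
once, its radical once; disproportionation returns half the rings to
the reduced pool, which preserves the same bookkeeping). Semiquinone
autoxidation by oxygen breaks this: each ring lost to O₂ has quenched
only once. With $\phi$ the fraction of semiquinones lost to oxygen, the
effective stoichiometry is $n = 2/(1+\phi)$, and at steady state
$\phi$ follows from $k'^2_{auto} = 2 k_{disp}\,\phi^2 R_i/(1-\phi)$
(with $k'_{auto} = k_{auto}[\mathrm{O_2}]$). Inverting this fixes the
class defaults: $k_{auto} = 0$ (chromanol, $n \to 2$), 120 M⁻¹s⁻¹
(ubiquinol, $n \approx 1.8$) and 3000 M⁻¹s⁻¹ (plastoquinol,
$n \approx 1$), matching the stoichiometries observed for these classes.
`effective_stoichiometry()` measures $n$ from the simulation by
integrating the two peroxyl-consuming fluxes to antioxidant exhaustion
(QH₂ below 0.1 % of its initial value); disproportionation is
deliberately not counted as quenching — it acts by extending the lag.

The quenching constant also differs by class: quinols use the generic
$k_{inh} = 3\times10^5$ M⁻¹s⁻¹ ($k_{inh}/k_p = 5000$), while the
chromanol default is $2.4\times10^4$ M⁻¹s⁻¹, chosen so that 1 µM of
α-tocopherol intercepts about every second radical against 400 µM of
tails (chain length ≈ 0.9, as observed). This reproduces the
qualitative ordering of the assay — quinols suppress the inhibited rate
far more strongly than chromanols, while chromanols protect longer.

### Aqueous competition (carrier-liposome delivery)

When the antioxidant sits in non-oxidizable carrier liposomes it can
only intercept water-borne initiator radicals.
`competition_slowdown()` implements the closed-form interception model
$1/(1-f)$ with $f = k_{inh}[AH]/(k_{inh}[AH]+k_p[\text{tails}])$
(13.5 at 1 µM antioxidant vs 400 µM tails) and a chain-amplified
variant that scales the propagation denominator by the chain length
(≈1.4 at defaults). Observed slowdowns fall between the two; since the
competition argument alone does not single out either formula, both are
exposed and neither is asserted against a particular measured factor.

## The synthetic-data generator

`synthesize_absorbance()` forward-transforms a simulation into the
instrument's record: A(234) = 27400·[diene], A(281) = Δε·[Q], additive
Gaussian noise of 0.002 absorbance units (the setup's noise floor),
5-minute sampling, seeded and reproducible without touching the
caller's RNG. `generate_fixture_panel()` assembles the default study:
five uninhibited runs (180 min) plus three replicates each of a
chromanol, a ubiquinol and a plastoquinol at 1 µM (300 min), with a
manifest holding two layers of ground truth:

* *protocol truth* — what the same analysis recovers from the noiseless
  trajectory (rates, lags); the yardstick for noise-robustness tests;
* *mechanistic truth* — the analytic lag $n_{eff}[AH]/R_i$ and
  $n_{eff}$ itself; the yardstick for the estimator-bias property above.

What the generator emulates: the lag/rise shape of diene kinetics, the
concurrent quinone rise and its plateau at antioxidant exhaustion,
delayed (30 min) antioxidant addition, the noise floor, and the
sampling grid. What it does not emulate: membrane partitioning and
inter-liposome transport, initiator depletion over long runs, baseline
drift, temperature fluctuations, or antioxidant loss during liposome
preparation — so passing recovery tests demonstrate correctness of the
analysis under the model's statistical assumptions, not robustness to
every artefact of real spectra.

Noise sets a floor on what recovery tests can demand: 0.002 AU is
7.3×10⁻⁸ M of dienes, which propagates to a one-sd slope uncertainty of
~0.6 nM/min over a typical plateau segment and ~2.8 nM/min over a
25-min window. The package's recovery tests therefore check 5 %
relative accuracy only for rates well above that floor (≥ 20 nM/min)
and an absolute ~3-sd band (2 nM/min) below it; lags are checked to
10 % and stoichiometries to 15 %. Problem sizes in the test suite — one
panel of 14 runs, 300 min horizons at 0.5 min resolution, a 1000-run
Gillespie comparison on a reduced counts-scale network — keep the full
suite under a minute while leaving every assertion statistically
meaningful.

## Numerical and design choices

* Wavelength lookup snaps to the nearest recorded column within 1 nm.
* Baseline policy: first-point absorbance by default (reference-cuvette
  subtraction removes static components, not the t = 0 offset); an
  explicit numeric baseline is accepted.
* Negative concentrations from noise are retained unclipped so rate
  fits stay unbiased; values below −3 noise sd trigger a warning.
* Cuvette path length defaults to 1 cm.
* The quinol quantitation coefficient (290 nm band: 4890/3940/3540/4140
  M⁻¹cm⁻¹ for ubiquinol-6/-10, plastoquinol-type, amphiphilic
  ubiquinol-type) and the kinetic difference coefficient at the 281 nm
  monitor wavelength are separate fields; in the absence of a dedicated
  difference coefficient the 290 nm value serves as a provisional
  default, and both are configurable.
* Flux calibration: the worked reproduction
  (`reproduce_reference_metrics()`) uses the 170 min reference lag that
  the published derivation used — calibrating from the replicate mean
  (171 min) shifts the uninhibited chain length from 28 to 29 and would
  no longer reproduce the printed table. The data-driven pipeline
  (`run_full_pipeline()`), by contrast, calibrates from the measured
  mean lag of the reference group, fitting each replicate and averaging
  durations (rather than averaging traces first).

## Limitations

The simulator is a bulk mass-action description; it has no membrane
geometry, so phenomena that hinge on partitioning (the factor-of-few
discrepancy of carrier-delivery competition, antioxidant exchange
between liposomes) are represented only by closed-form arguments. The
chain-carrier relaxation delay biases intersection lags upward for
short induction periods, as quantified above. Fits are rate/lag
summaries by design — there is no global nonlinear fit of full traces
to the ODE model.
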