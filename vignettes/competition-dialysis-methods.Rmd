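---
title: "Competition equilibrium dialysis: model, estimator, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition equilibrium dialysis: model, estimator, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialyzr)
library(dplyr)
```

## The assay and its model

Competition equilibrium dialysis (ED) estimates the apparent dissociation
constant $K_d$ of an antibody for a small-molecule drug without knowing the
antibody concentration — the property that makes it applicable to polyclonal
sera, where titers are measurable but absolute antibody concentrations are
not. A dialysis insert holds a 100 µL *sample chamber* (antibody + a labeled
tracer, here 5 nM of a deuterated drug analog) and a 300 µL *buffer chamber*
(the unlabeled competitive inhibitor), separated by a 12 kDa-cutoff membrane.
Small molecules cross freely; IgG does not. At equilibrium:

* the free concentration of each permeant ligand is equal in both chambers;
* bound ligand exists only in the sample chamber;
* with single-site competitive binding, site concentration $S$ and site
  dissociation constants $K_T$ (tracer) and $K_I$ (inhibitor), the bound
  tracer is
  $$\mathrm{bound}_T \;=\; \frac{S \, f/K_T}{1 + f/K_T + i/K_I},$$
  where $f$ and $i$ are the free tracer and inhibitor concentrations, and
  each ligand satisfies a mass balance over both chambers,
  $f\,(v_s + v_b) + \mathrm{bound}_T\, v_s = \text{amount loaded}$.

`solve_equilibrium()` solves this system exactly by bracketed bisection on
$f$ with an inner bracket on $i$ (both balances are monotone), to a root
tolerance of $10^{-12}$ nM, and verifies mass conservation to $10^{-9}$
relative before returning. `oracle_equilibrium()` implements the same
contract as plain nested interval halving with no shared code, so the two
routes can be compared on any cassette; the test suite does this over a
sampled grid of site concentrations (0–50 nM), affinities (0.1–100 nM) and
loadings (10–10⁴ nM·µL) and requires agreement within $10^{-6}$ nM.

Binding sites are parameterized as the *nominal antibody concentration* (one
effective site per IgG, `valence = 1` by default, adjustable). The affinity
tables this package targets are computed directly from nominal antibody
concentrations, and a valence factor would only rescale $S$; nothing in the
estimator consumes $S$ itself.

## The Müller estimator

The pipeline mirrors the classical competition-ED workflow:

1. **Bound fraction** $b = (c_s - c_b)/c_s$ from the zero-inhibitor
   condition, where $c_s$, $c_b$ are the tracer concentrations measured in
   the sample and buffer chambers. The buffer chamber sees only free tracer,
   so the chamber difference is the bound concentration.
2. **Total tracer concentration** $T_t = (c_s v_s + c_b v_b)/(v_s+v_b)$;
   with the standard 5 nM / 100 µL loading in a 400 µL insert, mass
   conservation pins $T_t$ at 1.25 nM.
3. **Percent inhibition** $100\,(1 - \mathrm{bound}_I/\mathrm{bound}_{I_0})$
   per titration level, and **$I_{50}$** by interpolation, linear in
   $\log_{10}$ of the inhibitor level between the first ascending pair that
   brackets 50 %. Log-linear interpolation is the natural choice for
   half-log-spaced titrations, where percent inhibition is near-linear in
   log concentration around the midpoint.
4. **Müller's equation**
   $$K_d = \big([I_{50}] - [T_t]\big)\big(1 - 1.5b + 0.5b^2\big).$$

Replicates are handled per triple by default: $b$, $I_{50}$ and $K_d$ are
computed for each replicate and summarized as mean ± SD, matching how
triplicate determinations are conventionally reported; `method = "pooled"`
averages concentrations first instead. On noiseless data the two coincide.

### Quality gates and classification

* **b window.** The estimator is only trusted for $b \in [0.4, 0.7]$.
  Outside the window the $K_d$ is still computed but flagged
  (`qc_b_window = "fail"`), because published affinity tables report all
  conditions while endorsing only the in-window ones — the out-of-window
  rows are precisely how the window's necessity is demonstrated. Whether
  the window, established with polyclonal sera, transfers quantitatively to
  monoclonal antibodies is an open question; the package flags rather than
  suppresses for this reason too.
* **Stability.** A drug that decays during the 24 h equilibration changes
  the analyte mixture and invalidates the estimate. The gate passes when at
  least 90 % of each analyte survives the incubation under the dataset's
  dilution/esterase conditions (the threshold is a package choice — the
  source experiments state conclusions per dilution, not a numeric cutoff —
  and is configurable).
* **Classification.** When the inhibition curve never crosses 50 %, or less
  than 5 % of tracer is bound, the result is classified instead of
  quantified: *no binding* below 5 % bound at 1:25 dilution, *low affinity*
  when binding is seen at 1:25 but lost at 1:400, per `classify_binding()`.
  A `kd_estimate` reports a numeric `kd` only when classification is
  `quantifiable`.

### The inhibitor concentration scale, and estimator bias

Müller's $[I_{50}]$ is a concentration, but a titration is defined by an
*amount* of inhibitor loaded into the 300 µL buffer chamber, and the
convention for expressing it is not fixed by the estimator's algebra. Two
scales are implemented:

* `"buffer-initial"` — amount / 300 µL, the concentration actually pipetted
  into the buffer chamber (**default**);
* `"total-volume"` — amount / 400 µL, the nominal whole-insert
  concentration.

The choice matters. `muller_bias_table()` characterizes the estimator
against the exact mass-action model (self-competition, exact $I_{50}$ by
root finding — no interpolation error):

```{r bias, eval = FALSE}
muller_bias_table(kd_true = c(0.5, 1, 2, 5),
                  b_targets = c(0.4, 0.5, 0.6, 0.7))
```

On the buffer-initial scale the estimate-to-truth ratio runs from about 1.2
(low $b$, low $K_d$) down to about 0.52 ($b = 0.7$, $K_d$ = 5 nM) — within
a factor of two everywhere on the 0.4–0.7 window, monotone decreasing in
$b$, and consistent with the benchmark recovery of a 2 nM monoclonal
standard at $b = 0.41$ (1.96 nM measured vs 2 nM reported). On the
total-volume scale the ratio falls to 0.38 at $b = 0.7$ — outside a factor
of two — which is why buffer-initial is the default. The package does not
assert that either convention is "the" historical one; both are exposed,
and the bias table documents the consequence of each.

## What the simulator emulates

`assay_design()` + `generate_dataset()` produce replicate-level "measured"
chamber concentrations so the entire pipeline is testable without
instrument data. The defaults are the assay's standard conditions:

* 100 µL + 300 µL cassette, 5 nM tracer in the sample chamber, inhibitor in
  the buffer chamber, impermeant antibody;
* triplicates with multiplicative lognormal noise, CV 2 % — the magnitude
  of printed replicate SDs (e.g. 59.68 ± 2.00 %) — mean-unbiased by
  construction;
* 24 h incubation; a matched negative-control condition (no antibody) in
  every dataset; 8 half-log-spaced titration levels bracketing the expected
  $I_{50}$ plus the zero level.

**Degradation.** Drugs decay with first-order kinetics; the total rate is a
buffer (spontaneous) component plus a serum component that scales inversely
with serum dilution and switches off above a per-drug inactivity dilution.
Calibrations, all stated as 24 h outcomes:

* heroin: buffer rate $\ln(1/0.799)/24 \approx 0.0094\;h^{-1}$, so 79.9 %
  survives 24 h in plain buffer; serum rate 0.125 h⁻¹ at 1:400, so < 5 %
  survives in serum at any practical dilution;
* 6-acetylmorphine: stable in buffer; serum component active below 1:200;
* morphine: stable in buffer; serum component active below 1:100 and — not
  being an ester — not rescued by esterase inhibitors;
* esterase inhibitors (iso-OMPA/BNPP) suppress the serum component of the
  ester drugs completely, reducing heroin's decay to its buffer rate.

Degradation is applied to total drug amounts *before* the equilibrium is
solved: over 24 h, decay and binding are treated as separable, consistent
with gating on stability rather than modeling coupled kinetics. The
dilution-threshold switch is a deliberate simplification: pure inverse
scaling cannot reproduce "no degradation observed at or above dilution X",
which is a statement about detectability within the assay window.

**Time courses.** `simulate_timecourse()` integrates two-compartment
exchange of free drug (flux proportional to the free-concentration
difference) with binding re-equilibrated at each step. `permeability` is
the passive relaxation rate of the chamber concentration difference; the
default $\ln(100)/6 \approx 0.77\;h^{-1}$ closes 99 % of that difference by
6 h, and predicts 60.0 % of tracer in the sample chamber at 3 h —
within one SD of the observed 59.68 ± 2.00 % — and a 50.0 % split at 24 h.
One permeability applies per cassette; the empirically slower equilibration
sometimes seen for the inhibitor relative to the tracer has no mechanism in
this model and is not reproduced.

**What passing tests do not show.** The generator draws independent
lognormal noise around exact mass-action values. Real readouts add
chromatographic drift, carryover, calibration-curve error and
matrix effects; real sera are polyclonal mixtures of affinities, while the
model has a single site class. Recovery results on synthetic data therefore
validate the *pipeline arithmetic and the estimator's intrinsic bias*, not
instrument performance, and the mechanistic-recovery property (factor of
two) should be read as the estimator's floor under ideal conditions, not
its accuracy on bench data.

## ELISA comparison

Plate-based competition ELISA reports IC₅₀ from a four-parameter logistic
fit of normalized response versus log inhibitor concentration. `fit_4pl()`
performs that fit (bounded Levenberg–Marquardt least squares; top/bottom
initialized from the response extremes, IC₅₀ from the level nearest
half-range, Hill slope 1; responses spanning < 10 % are flagged "no
inhibition" rather than fitted). The avidity gap between surface IC₅₀ and
solution $K_d$ is *not* modeled mechanistically — `simulate_elisa_curve()`
takes the true IC₅₀ as an input — because the comparison pipeline only
needs curves to exercise the fit. `ic50_kd_ratio()` joins the packaged
reference tables and reports IC₅₀/$K_d$ per serum–drug pair; censored
IC₅₀ cells ("> 1000 µM") and classified (low-affinity / no-binding) $K_d$
cells are never turned into numbers. Across the quantifiable pairs the
ratio spans roughly 10²–10⁴, the well-known avidity inflation of plate
IC₅₀ over solution affinity.

## Numerical choices and degenerate inputs

* Solver tolerance $10^{-12}$ nM; mass-balance residuals checked at
  $10^{-9}$ relative; no randomness anywhere in the solver.
* `Kd = Inf` denotes a non-binder; `site_conc = 0` short-circuits to the
  passive split (amount / 400 µL).
* $I_{50} < T_t$ (impossible negative $K_d$) yields `NA` with a warning.
* Negative measured bound concentrations (noise can make $c_b > c_s$) are
  clamped to zero with a warning; percent inhibition is clamped to
  [0, 100] likewise.
* A replicate whose inhibition curve never brackets 50 % contributes an
  `NA` $I_{50}$; if any replicate does so the summary $K_d$ is `NA` and the
  result is classified, never silently extrapolated.
* Problem sizes used in the shipped tests: 25-point property grids for
  solver–oracle agreement, 200 seeded repeats for noise robustness, 10⁴
  replicates for noise unbiasedness — sizes chosen so each property is
  measured well while the whole suite stays fast.

## Reproducibility

Every stochastic element (replicate noise, ELISA noise) flows from explicit
integer seeds; `generate_dataset()` and `run_workflow()` are byte-identical
under a fixed seed, and a workflow report carries a provenance record
(config hash, seed, package version) sufficient to re-run it exactly.
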