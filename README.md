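# dialyzr

Competition equilibrium dialysis (ED) affinity analysis for anti-drug
antibodies.

Vaccines against drugs of abuse work through antibodies that sequester the
drug before it crosses the blood–brain barrier, and their development hinges
on measuring how tightly those antibodies bind the drug and its metabolites.
Plate-based competition ELISA — the usual tool — inflates apparent affinities
by orders of magnitude through surface-avidity effects. Competition ED with a
labeled tracer measures the solution-phase apparent dissociation constant
K<sub>d</sub> instead, and works for polyclonal sera because the antibody
concentration never enters the calculation.

`dialyzr` implements that workflow end to end for people developing or
evaluating such assays:

* an **exact mass-action equilibrium solver** for tracer + competitive
  inhibitor + impermeant single-site antibody in a two-chamber cassette
  (`solve_equilibrium()`, with an independent brute-force cross-check
  `oracle_equilibrium()`);
* a **seeded synthetic-assay generator** — replicate noise, equilibration
  time courses, dilution-dependent first-order drug degradation and
  esterase-inhibitor rescue (`assay_design()`, `generate_dataset()`,
  `simulate_timecourse()`, `degradation_remaining()`);
* the **Müller estimation pipeline** from measured chamber concentrations to
  bound fraction *b*, total tracer concentration T<sub>t</sub>, interpolated
  I<sub>50</sub>, and

  K<sub>d</sub> = ([I<sub>50</sub>] − [T<sub>t</sub>]) (1 − 1.5*b* + 0.5*b*²),

  with QC gates (*b* window 0.4–0.7, drug-stability gate) and low-affinity /
  no-binding classification (`estimate_kd()`, `classify_binding()`);
* **competition-ELISA comparison**: four-parameter logistic IC₅₀ fitting and
  an IC₅₀-versus-K<sub>d</sub> discrepancy report over packaged reference
  tables (`fit_4pl()`, `ic50_kd_ratio()`).

Everything is tidyverse-native: pipeline functions take and return tibbles,
fitted objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

Simulate the benchmark cassette — 2.4 nM antibody sites of 2 nM affinity,
5 nM deuterated tracer, unlabeled drug titrated into the buffer chamber,
triplicates at 2 % CV — then estimate the affinity back:

```r
library(dialyzr)

design <- assay_design(site_conc = 2.4, tracer_kd = 2, inhibitor_kd = 2,
                       seed = 2024)
d <- generate_dataset(design)
est <- estimate_kd(d)
est
#> <kd_estimate> d3-morphine (per-replicate, buffer-initial scale)
#>   b    : 0.444 +/- 0.015  [window 0.4-0.7: pass]
#>   Tt   : 1.264 nM
#>   I50  : 5.69 +/- 0.99 nM
#>   Kd   : 1.92 +/- 0.5 nM
#>   QC stability: pass | classification: quantifiable
```

The bound fraction lands at 0.44 — inside the trusted 0.4–0.7 window — the
total tracer concentration recovers the theoretical 1.25 nM passive value
(5 nM × 100 µL spread over 400 µL), and the Müller estimate of 1.92 ± 0.5 nM
recovers the generative 2 nM affinity. `tidy(est)` returns the same numbers
as a one-row tibble; `autoplot(est$curve)` draws the inhibition curve.

The plate-versus-solution comparison over the packaged reference tables:

```r
dplyr::filter(ic50_kd_ratio(), serum == "6-AcMorHap")
#> # A tibble: 2 × 8
#>   serum      drug     kd_nM ic50_uM censored classification ratio status
#>   <chr>      <chr>    <dbl>   <dbl> <lgl>    <chr>          <dbl> <chr>
#> 1 6-AcMorHap 6-AM     0.563     1.1 FALSE    quantifiable   1954. ok
#> 2 6-AcMorHap morphine 0.555     0.1 FALSE    quantifiable    180. ok
```

A plate IC₅₀ of 1.1 µM against a solution K<sub>d</sub> of 0.563 nM is a
~2000-fold avidity inflation; across all quantifiable serum–drug pairs the
gap spans roughly 10²–10⁴.

See the vignette (`vignettes/competition-dialysis-methods.Rmd`) for the
model, the estimator's bias characterization (`muller_bias_table()`), the
degradation calibrations, and the design decisions.

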