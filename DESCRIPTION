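Package: dialyzr
Title: Competition Equilibrium Dialysis Affinity Analysis for Anti-Drug Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating apparent dissociation constants (Kd) of
    drug-binding antibodies from two-chamber competition equilibrium dialysis
    assays with labeled tracers. Provides an exact mass-action equilibrium
    solver for tracer + competitive inhibitor + impermeant single-site
    antibody, a seeded synthetic-assay generator (chamber time courses,
    replicate noise, dilution-dependent first-order drug degradation and
    esterase-inhibitor rescue), the Mueller-equation estimation pipeline
    (bound fraction b, total tracer concentration, I50 interpolation, QC
    gates, binding classification), and four-parameter logistic competition
    ELISA IC50 fitting with an IC50-versus-Kd comparison over packaged
    reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
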