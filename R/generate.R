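# Synthetic-assay generator: turns a physical cassette description into the
# tidy replicate-level "measured" concentration table the estimation pipeline
# consumes, standing in for the instrument readout.

#' Describe one competition-dialysis assay run
#'
#' Bundles everything needed to simulate a titration experiment: the cassette,
#' the generative affinities, the serum dilution, the inhibitor titration, the
#' replicate/noise structure and the degradation conditions. The defaults are
#' the assay's standard conditions: 100 + 300 uL insert, 5 nM tracer,
#' triplicates with 2 % CV, 24 h incubation.
#'
#' @param site_conc Antibody binding-site concentration (nM) in the test
#'   cassettes. A matched negative-control condition (site_conc = 0) is always
#'   generated alongside.
#' @param tracer_name,tracer_kd,tracer_conc Tracer identity, generative site
#'   Kd (nM) and loading concentration (nM, sample chamber).
#' @param inhibitor_name,inhibitor_kd Inhibitor identity and generative site
#'   Kd (nM).
#' @param inhibitor_amounts Inhibitor loadings (nM*uL, buffer chamber) for the
#'   titration. 0 (the b-determination condition) is always included. The
#'   default `NULL` builds 8 half-log-spaced levels bracketing the expected
#'   I50 from the generative parameters.
#' @param dilution Serum dilution fold (or `Inf` for pure buffer).
#' @param esterase_inhibitors Logical; iso-OMPA/BNPP present?
#' @param replicates Replicate measurements per condition (default 3).
#' @param noise_cv Multiplicative lognormal coefficient of variation of a
#'   measured concentration (default 0.02).
#' @param incubation_h Equilibration time in hours (default 24).
#' @param geometry A [dialysis_geometry()].
#' @param scale Inhibitor-level reporting scale, see [level_from_amount()].
#' @param degradation A [degradation_model()] rate table.
#' @param seed Integer seed for reproducible noise, or `NULL`.
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(site_conc = 2.4, tracer_kd = 2, inhibitor_kd = 2, seed = 1)
#' @export
assay_design <- function(site_conc = 2.4,
                         tracer_name = "d3-morphine", tracer_kd = 2,
                         tracer_conc = 5,
                         inhibitor_name = "morphine", inhibitor_kd = 2,
                         inhibitor_amounts = NULL,
                         dilution = 400, esterase_inhibitors = FALSE,
                         replicates = 3, noise_cv = 0.02, incubation_h = 24,
                         geometry = dialysis_geometry(),
                         scale = c("buffer-initial", "total-volume"),
                         degradation = degradation_model(),
                         seed = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(replicates), replicates >= 1,
            is.numeric(noise_cv), noise_cv >= 0,
            is.numeric(incubation_h), incubation_h >= 0,
            inherits(geometry, "dialysis_geometry"))
  if (is.null(inhibitor_amounts)) {
    # 8 half-log levels bracketing the expected I50 of the generative model
    i50_guess <- tracer_kd / correction_factor(0.5) +
      tracer_conc * geometry$v_sample / geometry$v_total
    center <- amount_from_level(i50_guess, geometry, scale)
    inhibitor_amounts <- center * 10^seq(-1.75, 1.75, by = 0.5)
  }
  inhibitor_amounts <- sort(unique(c(0, inhibitor_amounts)))
  structure(
    list(site_conc = site_conc,
         tracer_name = tracer_name, tracer_kd = tracer_kd,
         tracer_conc = tracer_conc,
         inhibitor_name = inhibitor_name, inhibitor_kd = inhibitor_kd,
         inhibitor_amounts = inhibitor_amounts,
         dilution = dilution, esterase_inhibitors = esterase_inhibitors,
         replicates = as.integer(replicates), noise_cv = noise_cv,
         incubation_h = incubation_h, geometry = geometry, scale = scale,
         degradation = degradation, seed = seed),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat("<assay_design>\n")
  cat(sprintf("  sites %g nM | tracer %s (Kd %g nM, %g nM) | inhibitor %s (Kd %g nM)\n",
              x$site_conc, x$tracer_name, x$tracer_kd, x$tracer_conc,
              x$inhibitor_name, x$inhibitor_kd))
  cat(sprintf("  %d titration levels | dilution 1:%g | %d replicates, CV %g | %g h\n",
              length(x$inhibitor_amounts), x$dilution, x$replicates,
              x$noise_cv, x$incubation_h))
  invisible(x)
}

# multiplicative lognormal noise with unit mean and the given CV
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a replicate-level measured dataset from an assay design
#'
#' For every condition (each inhibitor titration level plus a matched
#' negative control with no antibody) the cassette equilibrium is solved
#' after applying first-order degradation to the total drug amounts over the
#' incubation time (degradation and binding are treated as separable), and
#' replicate chamber concentrations are emitted with independent
#' multiplicative lognormal noise. Fully reproducible under a fixed seed.
#'
#' @param design An [assay_design()].
#' @return A tibble of class `measured_dataset` with columns `condition_id`,
#'   `inhibitor_level_nM` (reporting scale), `chamber`, `analyte`,
#'   `replicate`, `conc_nM`, `dilution`, `esterase_inhibitors`. The design is
#'   attached as attribute `"design"`.
#' @examples
#' d <- generate_dataset(assay_design(seed = 42))
#' dplyr::count(d, condition_id)
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  geo <- design$geometry

  if (!is.null(design$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(design$seed)
  }

  keep_t <- degradation_remaining(design$tracer_name, design$dilution,
                                  design$esterase_inhibitors,
                                  design$incubation_h, design$degradation)
  keep_i <- degradation_remaining(design$inhibitor_name, design$dilution,
                                  design$esterase_inhibitors,
                                  design$incubation_h, design$degradation)

  one_condition <- function(id, site, amount_i) {
    tr <- ligand(design$tracer_name, design$tracer_kd,
                 design$tracer_conc * geo$v_sample * keep_t, "sample")
    inh <- if (amount_i > 0) {
      ligand(design$inhibitor_name, design$inhibitor_kd,
             amount_i * keep_i, "buffer")
    } else NULL
    st <- solve_equilibrium(binding_system(site, tr, inh, geo))
    level <- level_from_amount(amount_i, geo, design$scale)

    rows <- tibble::tibble(
      chamber = c("sample", "buffer"),
      analyte = design$tracer_name,
      true_nM = c(st$total_tracer_sample, st$total_tracer_buffer)
    )
    if (amount_i > 0) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        chamber = c("sample", "buffer"),
        analyte = design$inhibitor_name,
        true_nM = c(st$total_inhibitor_sample, st$total_inhibitor_buffer)
      ))
    }
    rows <- tidyr::crossing(rows, replicate = seq_len(design$replicates))
    rows$conc_nM <- rows$true_nM * .lnoise(nrow(rows), design$noise_cv)
    tibble::tibble(
      condition_id = id,
      inhibitor_level_nM = level,
      chamber = rows$chamber,
      analyte = rows$analyte,
      replicate = rows$replicate,
      conc_nM = rows$conc_nM,
      dilution = design$dilution,
      esterase_inhibitors = design$esterase_inhibitors
    )
  }

  amounts <- design$inhibitor_amounts
  ids <- sprintf("test_I%02d", seq_along(amounts) - 1L)
  out <- purrr::map2(ids, amounts,
                     function(id, a) one_condition(id, design$site_conc, a))
  out[[length(out) + 1]] <- one_condition("negative_control", 0, 0)
  out <- dplyr::bind_rows(out)
  class(out) <- c("measured_dataset", class(out))
  attr(out, "design") <- design
  out
}
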