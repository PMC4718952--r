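# Characterization of the Mueller estimator against the exact mass-action
# model: the estimator is consistent only up to the approximations baked into
# the correction factor, and its bias depends on b and on the inhibitor
# reporting scale.

#' Antibody site concentration that yields a target bound fraction
#'
#' Solves (by bracketed root finding on the no-inhibitor equilibrium) for the
#' binding-site concentration at which the tracer bound fraction b equals
#' `b_target`, given the tracer affinity and loading. Used to steer simulated
#' assays into the valid 0.4-0.7 estimation window.
#'
#' @param b_target Desired bound fraction in (0, 1).
#' @param tracer_kd Tracer site Kd in nM.
#' @param tracer_conc Tracer loading concentration (nM, sample chamber).
#' @param geometry A [dialysis_geometry()].
#' @return Site concentration in nM.
#' @examples
#' site_conc_for_b(0.5, tracer_kd = 2)
#' @export
site_conc_for_b <- function(b_target, tracer_kd, tracer_conc = 5,
                            geometry = dialysis_geometry()) {
  stopifnot(is.numeric(b_target), length(b_target) == 1,
            b_target > 0, b_target < 1)
  b_of <- function(s) {
    st <- solve_equilibrium(binding_system(
      s, tracer_ligand(kd_site = tracer_kd, conc_nM = tracer_conc,
                       geometry = geometry),
      geometry = geometry))
    st$bound_tracer / st$total_tracer_sample - b_target
  }
  hi <- 10
  while (b_of(hi) < 0 && hi < 1e9) hi <- hi * 10
  stats::uniroot(b_of, c(1e-9, hi), tol = 1e-12)$root
}

#' Bias of the Mueller Kd estimate on exact mass-action data
#'
#' For a grid of true Kd values and target bound fractions, steers the
#' antibody concentration so b hits its target, locates the exact I50 of the
#' noiseless mass-action inhibition curve (self-competition: the unlabeled
#' drug shares the tracer's affinity) by root finding, and applies the
#' Mueller equation. The ratio of estimate to truth characterizes the
#' estimator's systematic bias, which depends on b (monotonically) and on the
#' inhibitor reporting scale.
#'
#' @param kd_true True site Kd values in nM.
#' @param b_targets Bound fractions to steer to.
#' @param scale Inhibitor-level reporting scale entering `[I50]`.
#' @param tracer_conc Tracer loading (nM).
#' @param geometry A [dialysis_geometry()].
#' @return A tibble: `kd_true`, `b_target`, `b`, `site_conc`, `tt_nM`,
#'   `i50_nM`, `kd_est`, `ratio` (`kd_est / kd_true`).
#' @examples
#' muller_bias_table(kd_true = 2, b_targets = c(0.4, 0.7))
#' @export
muller_bias_table <- function(kd_true = c(0.5, 1, 2, 5),
                              b_targets = c(0.4, 0.5, 0.6, 0.7),
                              scale = c("buffer-initial", "total-volume"),
                              tracer_conc = 5,
                              geometry = dialysis_geometry()) {
  scale <- match.arg(scale)
  grid <- tidyr::crossing(kd_true = kd_true, b_target = b_targets)
  purrr::pmap_dfr(grid, function(kd_true, b_target) {
    s <- site_conc_for_b(b_target, kd_true, tracer_conc, geometry)
    base <- binding_system(
      s, tracer_ligand(kd_site = kd_true, conc_nM = tracer_conc,
                       geometry = geometry),
      inhibitor = ligand("inhibitor", kd_site = kd_true, amount = 0,
                         chamber = "buffer"),
      geometry = geometry)
    st0 <- solve_equilibrium(base)
    b <- st0$bound_tracer / st0$total_tracer_sample
    tt <- compute_tt(st0$total_tracer_sample, st0$total_tracer_buffer,
                     geometry)
    inh_at <- function(a) {
      sys <- base
      sys$inhibitor$amount <- a
      100 * (1 - solve_equilibrium(sys)$bound_tracer / st0$bound_tracer)
    }
    hi <- geometry$v_total
    while (inh_at(hi) < 50 && hi < 1e12) hi <- hi * 10
    a50 <- stats::uniroot(function(a) inh_at(a) - 50, c(1e-6, hi),
                          tol = 1e-9)$root
    i50 <- level_from_amount(a50, geometry, scale)
    kd_est <- muller_kd(i50, tt, b)
    tibble::tibble(kd_true = kd_true, b_target = b_target, b = b,
                   site_conc = s, tt_nM = tt, i50_nM = i50,
                   kd_est = kd_est, ratio = kd_est / kd_true)
  })
}
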