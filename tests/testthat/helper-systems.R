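# shared builders for test cassettes and hand-made measured datasets

std_geometry <- function() dialysis_geometry(100, 300)

# the standard monoclonal check case: 2.4 nM sites, Kd 2 nM, 5 nM tracer
monoclonal_system <- function(site_conc = 2.4, kd = 2, inhibitor_amount = 0) {
  inh <- if (!is.null(inhibitor_amount)) {
    ligand("morphine", kd_site = kd, amount = inhibitor_amount,
           chamber = "buffer")
  } else NULL
  binding_system(site_conc,
                 tracer_ligand("d3-morphine", kd_site = kd, conc_nM = 5),
                 inhibitor = inh)
}

# independent 1-D mass-balance reference for the no-inhibitor case:
# V*f + v_s*S*f/(K+f) = amount, solved by base-R uniroot
ref_free_tracer <- function(site, kd, amount = 500, vs = 100, vb = 300) {
  if (site == 0 || is.infinite(kd)) return(amount / (vs + vb))
  stats::uniroot(function(f) (vs + vb) * f + vs * site * f / (kd + f) - amount,
                 c(0, amount / (vs + vb)), tol = 1e-14)$root
}

# hand-construct a Mueller-consistent noiseless measured dataset: chamber
# concentrations whose pipeline output recovers (kd, b, tt) exactly.
# Levels are placed symmetrically in log10 around the implied I50 so the
# log-linear interpolation crosses 50 % at exactly that level.
muller_consistent_dataset <- function(kd, b, tt, replicates = 3,
                                      dilution = 400) {
  stopifnot(b > 0, b < 1)
  cf <- correction_factor(b)
  i50 <- kd / cf + tt
  c_s0 <- 400 * tt / (100 + 300 * (1 - b))
  c_b0 <- c_s0 * (1 - b)
  bound0 <- c_s0 - c_b0

  levels <- i50 * 10^c(-0.9, -0.3, 0.3, 0.9)
  pct <- c(20, 40, 60, 80)

  rows <- list()
  add <- function(id, level, c_s, c_b) {
    rows[[length(rows) + 1]] <<- tidyr::crossing(
      tibble::tibble(condition_id = id, inhibitor_level_nM = level,
                     chamber = c("sample", "buffer"),
                     analyte = "d3-morphine", conc_nM = c(c_s, c_b)),
      replicate = seq_len(replicates))
  }
  add("test_I00", 0, c_s0, c_b0)
  for (j in seq_along(levels)) {
    bound <- bound0 * (1 - pct[j] / 100)
    add(sprintf("test_I%02d", j), levels[j], c_b0 + bound, c_b0)
  }
  add("negative_control", 0, 1.25, 1.25)
  out <- dplyr::bind_rows(rows)
  out$dilution <- dilution
  out$esterase_inhibitors <- FALSE
  out <- out[, c("condition_id", "inhibitor_level_nM", "chamber", "analyte",
                 "replicate", "conc_nM", "dilution", "esterase_inhibitors")]
  class(out) <- c("measured_dataset", class(out))
  out
}

# exact I50 of a mechanistic system found by root bracketing on percent
# inhibition computed from the brute-force oracle at a fine quarter-log grid
oracle_i50_amount <- function(system) {
  s0 <- system
  s0$inhibitor$amount <- 0
  b0 <- oracle_equilibrium(s0)$bound_tracer
  grid <- 10^seq(1, 7, by = 0.25)
  pct <- vapply(grid, function(a) {
    s <- system
    s$inhibitor$amount <- a
    100 * (1 - oracle_equilibrium(s)$bound_tracer / b0)
  }, numeric(1))
  j <- which(pct[-length(pct)] < 50 & pct[-1] > 50)[1]
  lx <- log10(grid[j]) + (50 - pct[j]) / (pct[j + 1] - pct[j]) * 0.25
  10^lx
}
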