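# Mass-action equilibrium of tracer + competitive inhibitor + impermeant
# single-site antibody across a two-chamber cassette.
#
# At equilibrium the free concentration of each permeant ligand is equal in
# both chambers (call it f for the tracer, i for the inhibitor); bound ligand
# exists only in the sample chamber. With S the site concentration and
# K_T, K_I the site dissociation constants, single-site competitive occupancy
# gives
#   bound_T = S * (f/K_T) / (1 + f/K_T + i/K_I)
# and each ligand must satisfy its mass balance over both chambers:
#   f * (v_s + v_b) + bound_T * v_s = amount_T.
# The solver brackets f with an inner bracket on i (both monotone), per the
# nested 1-D root strategy; no randomness, tolerance 1e-12 nM.

# fraction of sites denominators; Inf Kd => the species never binds
.kd_ratio <- function(conc, kd) if (is.infinite(kd)) 0 else conc / kd

.solve_inner_inhibitor <- function(f_t, sys) {
  inh <- sys$inhibitor
  if (is.null(inh) || inh$amount <= 0) return(0)
  V <- sys$geometry$v_total
  vs <- sys$geometry$v_sample
  S <- sys$site_conc
  if (is.infinite(inh$kd_site) || S <= 0) return(inh$amount / V)
  bal <- function(fi) {
    denom <- 1 + .kd_ratio(f_t, sys$tracer$kd_site) + fi / inh$kd_site
    V * fi + vs * S * (fi / inh$kd_site) / denom - inh$amount
  }
  upper <- inh$amount / V
  if (bal(upper) <= 0) return(upper)  # numerically free everywhere
  stats::uniroot(bal, c(0, upper), tol = 1e-14, maxiter = 1000)$root
}

#' Solve the cassette mass-action equilibrium
#'
#' Computes the exact competitive single-site equilibrium of a
#' [binding_system()]: equal free ligand concentrations across chambers,
#' bound ligand confined to the sample chamber, both mass balances satisfied
#' simultaneously. Solved by bracketed bisection on the free tracer with an
#' inner bracket on the free inhibitor (deterministic, tolerance 1e-12 nM);
#' the residual relative mass-balance error is checked against 1e-9 and a
#' solver error is raised if it is exceeded.
#'
#' @param system A [binding_system()].
#' @return A one-row tibble of class `equilibrium_state` with columns
#'   `free_tracer`, `free_inhibitor`, `bound_tracer`, `bound_inhibitor`,
#'   `total_tracer_sample`, `total_tracer_buffer`,
#'   `total_inhibitor_sample`, `total_inhibitor_buffer` (all nM) and the
#'   relative mass-balance residuals `residual_tracer`, `residual_inhibitor`.
#' @examples
#' sys <- binding_system(
#'   site_conc = 2.4,
#'   tracer = tracer_ligand("d3-morphine", kd_site = 2, conc_nM = 5)
#' )
#' solve_equilibrium(sys)
#' @seealso [oracle_equilibrium()] for an independent brute-force check.
#' @export
solve_equilibrium <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  geo <- system$geometry
  V <- geo$v_total
  vs <- geo$v_sample
  S <- system$site_conc
  tr <- system$tracer
  if (tr$amount <= 0) {
    rlang::abort("tracer amount must be > 0", class = "dialyzr_invalid")
  }

  if (S <= 0 || is.infinite(tr$kd_site)) {
    f_t <- tr$amount / V
    f_i <- .solve_inner_inhibitor(f_t, system)
  } else {
    outer_bal <- function(f) {
      fi <- .solve_inner_inhibitor(f, system)
      denom <- 1 + f / tr$kd_site + .kd_ratio(fi, .inh_kd(system))
      V * f + vs * S * (f / tr$kd_site) / denom - tr$amount
    }
    upper <- tr$amount / V
    if (outer_bal(upper) <= 0) {
      f_t <- upper
    } else {
      f_t <- stats::uniroot(outer_bal, c(0, upper),
                            tol = 1e-14, maxiter = 1000)$root
    }
    f_i <- .solve_inner_inhibitor(f_t, system)
  }

  .finish_state(system, f_t, f_i)
}

.inh_kd <- function(sys) if (is.null(sys$inhibitor)) Inf else sys$inhibitor$kd_site

# assemble an equilibrium_state tibble from free concentrations and verify
# mass conservation to 1e-9 relative
.finish_state <- function(system, f_t, f_i, check = TRUE) {
  geo <- system$geometry
  V <- geo$v_total
  vs <- geo$v_sample
  S <- system$site_conc
  kt <- system$tracer$kd_site
  ki <- .inh_kd(system)
  denom <- 1 + .kd_ratio(f_t, kt) + .kd_ratio(f_i, ki)
  bound_t <- if (S > 0) S * .kd_ratio(f_t, kt) / denom else 0
  bound_i <- if (S > 0) S * .kd_ratio(f_i, ki) / denom else 0

  amt_t <- system$tracer$amount
  amt_i <- if (is.null(system$inhibitor)) 0 else system$inhibitor$amount
  res_t <- abs(V * f_t + vs * bound_t - amt_t) / max(amt_t, 1e-300)
  res_i <- if (amt_i > 0) abs(V * f_i + vs * bound_i - amt_i) / amt_i else 0
  if (check && (res_t > 1e-9 || res_i > 1e-9)) {
    rlang::abort(
      sprintf("equilibrium solver did not converge (relative residuals %.3g tracer, %.3g inhibitor)",
              res_t, res_i),
      class = "dialyzr_solver_error"
    )
  }

  out <- tibble::tibble(
    free_tracer = f_t,
    free_inhibitor = f_i,
    bound_tracer = bound_t,
    bound_inhibitor = bound_i,
    total_tracer_sample = f_t + bound_t,
    total_tracer_buffer = f_t,
    total_inhibitor_sample = f_i + bound_i,
    total_inhibitor_buffer = f_i,
    residual_tracer = res_t,
    residual_inhibitor = res_i
  )
  class(out) <- c("equilibrium_state", class(out))
  attr(out, "system") <- system
  out
}

#' Brute-force equilibrium reference (independent of the solver)
#'
#' Identical contract to [solve_equilibrium()] but implemented as exhaustive
#' nested interval halving over (free tracer, free inhibitor) with no code
#' shared with the production solver. Intended as an independent cross-check;
#' it is slower and exists so the solver's correctness can be verified on any
#' system.
#'
#' @inheritParams solve_equilibrium
#' @return As [solve_equilibrium()].
#' @examples
#' sys <- binding_system(2.4, tracer_ligand(kd_site = 2))
#' oracle_equilibrium(sys)
#' @export
oracle_equilibrium <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  vs <- system$geometry$v_sample
  vb <- system$geometry$v_buffer
  V <- vs + vb
  S <- system$site_conc
  kt <- system$tracer$kd_site
  ki <- if (is.null(system$inhibitor)) Inf else system$inhibitor$kd_site
  at <- system$tracer$amount
  ai <- if (is.null(system$inhibitor)) 0 else system$inhibitor$amount
  if (at <= 0) {
    rlang::abort("tracer amount must be > 0", class = "dialyzr_invalid")
  }

  rat <- function(conc, kd) if (is.infinite(kd)) 0 else conc / kd

  # inhibitor imbalance at (f, i); increasing in i
  imbal_i <- function(f, i) {
    d <- 1 + rat(f, kt) + rat(i, ki)
    V * i + vs * S * rat(i, ki) / d - ai
  }
  halve_i <- function(f) {
    if (ai <= 0) return(0)
    lo <- 0; hi <- ai / V
    if (imbal_i(f, hi) <= 0) return(hi)
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (imbal_i(f, mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  # tracer imbalance at f with the inhibitor self-consistent; increasing in f
  imbal_t <- function(f) {
    i <- halve_i(f)
    d <- 1 + rat(f, kt) + rat(i, ki)
    V * f + vs * S * rat(f, kt) / d - at
  }

  lo <- 0; hi <- at / V
  if (imbal_t(hi) <= 0) {
    f_t <- hi
  } else {
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (imbal_t(mid) > 0) hi <- mid else lo <- mid
    }
    f_t <- (lo + hi) / 2
  }
  .finish_state(system, f_t, halve_i(f_t))
}

#' Mueller bound-fraction correction factor
#'
#' The correction term `1 - 1.5 b + 0.5 b^2` (algebraically
#' `(1 - b)(1 - b/2)`) applied to the competition-dialysis Kd estimate, where
#' `b` is the fraction of tracer bound in the absence of inhibitor.
#'
#' @param b Bound tracer fraction(s) in `[0, 1]`.
#' @return The correction factor(s), dimensionless in `[0, 1]`.
#' @examples
#' correction_factor(c(0, 0.41, 1))
#' @export
correction_factor <- function(b) {
  stopifnot(is.numeric(b))
  if (any(!is.finite(b)) || any(b < 0 | b > 1)) {
    rlang::abort("b must lie in [0, 1]", class = "dialyzr_invalid")
  }
  1 - 1.5 * b + 0.5 * b^2
}

#' Apparent dissociation constant from competition dialysis (Mueller's equation)
#'
#' `Kd = (I50 - Tt) * (1 - 1.5 b + 0.5 b^2)`, where `I50` is the inhibitor
#' concentration producing 50 % inhibition of tracer binding, `Tt` the total
#' tracer concentration in the system after equilibration, and `b` the bound
#' tracer fraction without inhibitor.
#'
#' @param i50 I50 in nM (vectorized).
#' @param t_t Total tracer concentration after equilibrium, nM.
#' @param b Bound tracer fraction(s) in `[0, 1]`.
#' @return Kd in nM; `NA` with a warning where `i50 < t_t` (a negative Kd is
#'   physically impossible and marks an invalid estimate).
#' @examples
#' muller_kd(3.25, 1.25, 0)      # unit correction factor
#' muller_kd(5.43, 1.25, 0.41)   # ~1.96 nM
#' @export
muller_kd <- function(i50, t_t, b) {
  stopifnot(is.numeric(i50), is.numeric(t_t))
  cf <- correction_factor(b)
  out <- (i50 - t_t) * cf
  bad <- !is.na(out) & i50 < t_t
  if (any(bad)) {
    rlang::warn("i50 < t_t: invalid (negative) Kd estimate set to NA")
    out[bad] <- NA_real_
  }
  out
}

#' Noiseless inhibition curve predicted by the mass-action model
#'
#' Solves the cassette equilibrium at each inhibitor loading and expresses the
#' suppression of bound tracer as percent inhibition relative to the
#' zero-inhibitor condition. Inhibitor levels are reported on the chosen
#' concentration scale (see Details).
#'
#' @details Two reporting scales are supported for the inhibitor level: the
#'   initial buffer-chamber concentration (`amount / v_buffer`, the
#'   concentration actually pipetted into the buffer chamber; the default) and
#'   the nominal whole-insert concentration (`amount / v_total`). The choice
#'   propagates into the I50 read off the curve and hence into the Mueller Kd;
#'   see [muller_bias_table()] for its quantitative effect.
#'
#' @param system A [binding_system()] with a non-`NULL` inhibitor (its
#'   `amount` is overridden by `inhibitor_amounts`).
#' @param inhibitor_amounts Ascending inhibitor loadings in nM*uL, at least
#'   two levels including 0.
#' @param scale `"buffer-initial"` or `"total-volume"`.
#' @return A tibble of class `inhibition_curve` with columns `level_nM`,
#'   `pct_inhibition`, `sd`, `n` (noiseless prediction: `sd = 0`, `n = 1`);
#'   attributes `scale` and `bound_I0`.
#' @examples
#' sys <- binding_system(
#'   2.4, tracer_ligand(kd_site = 2),
#'   inhibitor = ligand("morphine", kd_site = 2, amount = 0, chamber = "buffer")
#' )
#' predict_inhibition_curve(sys, c(0, 10^seq(1, 4, 0.5)) * 400)
#' @export
predict_inhibition_curve <- function(system, inhibitor_amounts,
                                     scale = c("buffer-initial",
                                               "total-volume")) {
  scale <- match.arg(scale)
  stopifnot(inherits(system, "binding_system"),
            is.numeric(inhibitor_amounts), length(inhibitor_amounts) >= 2)
  if (is.null(system$inhibitor)) {
    rlang::abort("system must carry an inhibitor ligand",
                 class = "dialyzr_invalid")
  }
  if (is.unsorted(inhibitor_amounts, strictly = TRUE) ||
      inhibitor_amounts[1] != 0) {
    rlang::abort("inhibitor_amounts must be strictly ascending and include 0",
                 class = "dialyzr_invalid")
  }

  states <- purrr::map(inhibitor_amounts, function(a) {
    s <- system
    s$inhibitor$amount <- a
    solve_equilibrium(s)
  })
  bound <- purrr::map_dbl(states, "bound_tracer")
  if (bound[1] <= 0) {
    rlang::abort("zero-inhibitor bound tracer is 0: inhibition undefined",
                 class = "dialyzr_invalid")
  }
  out <- tibble::tibble(
    level_nM = level_from_amount(inhibitor_amounts, system$geometry, scale),
    pct_inhibition = 100 * (1 - bound / bound[1]),
    sd = 0,
    n = 1L
  )
  class(out) <- c("inhibition_curve", class(out))
  attr(out, "scale") <- scale
  attr(out, "bound_I0") <- bound[1]
  out
}

#' Convert between inhibitor amount and reported concentration level
#'
#' @param amount Inhibitor loading(s) in nM*uL.
#' @param geometry A [dialysis_geometry()].
#' @param scale `"buffer-initial"` (amount / v_buffer) or `"total-volume"`
#'   (amount / v_total).
#' @return Level(s) in nM.
#' @examples
#' level_from_amount(1333.3 * 300, dialysis_geometry(), "total-volume")
#' @export
level_from_amount <- function(amount, geometry = dialysis_geometry(),
                              scale = c("buffer-initial", "total-volume")) {
  scale <- match.arg(scale)
  amount / switch(scale,
                  "buffer-initial" = geometry$v_buffer,
                  "total-volume" = geometry$v_total)
}

#' @rdname level_from_amount
#' @param level Level(s) in nM on the given scale.
#' @export
amount_from_level <- function(level, geometry = dialysis_geometry(),
                              scale = c("buffer-initial", "total-volume")) {
  scale <- match.arg(scale)
  level * switch(scale,
                 "buffer-initial" = geometry$v_buffer,
                 "total-volume" = geometry$v_total)
}
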