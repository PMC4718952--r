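# Estimation pipeline: from measured chamber concentrations to b, Tt, I50,
# the Mueller Kd, QC gates and a binding classification.

#' Percent of drug found in one chamber
#'
#' `100 * c_chamber / (c_sample + c_buffer)`: how the equilibration of a
#' permeant drug between the two chambers is reported.
#'
#' @param conc_sample,conc_buffer Chamber concentrations (nM), vectorized.
#' @param chamber Which chamber to express, `"sample"` or `"buffer"`.
#' @return Percent in `[0, 100]`.
#' @examples
#' percent_drug(1, 1)       # 50
#' percent_drug(3, 1)       # 75
#' @export
percent_drug <- function(conc_sample, conc_buffer,
                         chamber = c("sample", "buffer")) {
  chamber <- match.arg(chamber)
  tot <- conc_sample + conc_buffer
  if (any(tot <= 0, na.rm = TRUE)) {
    rlang::abort("conc_sample + conc_buffer must be > 0",
                 class = "dialyzr_invalid")
  }
  100 * (if (chamber == "sample") conc_sample else conc_buffer) / tot
}

#' Percent of drug remaining relative to its initial concentration
#'
#' @param conc_t Concentration at time t (nM).
#' @param conc_initial Initial concentration (nM, > 0).
#' @return Percent remaining.
#' @examples
#' percent_remaining(4, 5)  # 80
#' @export
percent_remaining <- function(conc_t, conc_initial) {
  if (any(conc_initial <= 0, na.rm = TRUE)) {
    rlang::abort("conc_initial must be > 0", class = "dialyzr_invalid")
  }
  100 * conc_t / conc_initial
}

#' Bound tracer fraction b from chamber concentrations
#'
#' `b = (c_sample - c_buffer) / c_sample`: the buffer chamber holds only free
#' tracer, whose concentration equals the free tracer in the sample chamber,
#' so the chamber difference is the bound concentration. Negative values
#' (possible under measurement noise) are clamped to 0 with a warning.
#'
#' @param conc_sample,conc_buffer Tracer concentrations (nM) in the sample and
#'   buffer chambers, vectorized.
#' @return Bound fraction(s) in `[0, 1]`.
#' @examples
#' compute_b(1.864, 1.042)  # ~0.441
#' @export
compute_b <- function(conc_sample, conc_buffer) {
  if (any(conc_sample <= 0, na.rm = TRUE)) {
    rlang::abort("conc_sample must be > 0", class = "dialyzr_invalid")
  }
  b <- (conc_sample - conc_buffer) / conc_sample
  if (any(b < 0, na.rm = TRUE)) {
    rlang::warn("negative bound fraction clamped to 0 (c_buffer > c_sample)")
    b <- pmax(b, 0)
  }
  b
}

#' Percent bound heroin from chamber concentrations
#'
#' Identical in form to [compute_b()] but reported as a percentage; used when
#' degradation precludes a Kd and the bound percentage itself is the readout
#' (heroin in the presence of esterase inhibitors).
#'
#' @inheritParams compute_b
#' @return Percent bound in `[0, 100]`.
#' @examples
#' percent_bound_heroin(2, 1)  # 50
#' @export
percent_bound_heroin <- function(conc_sample, conc_buffer) {
  100 * compute_b(conc_sample, conc_buffer)
}

#' Total tracer concentration after equilibrium (Tt)
#'
#' Volume-weighted whole-insert concentration
#' `(c_sample * v_sample + c_buffer * v_buffer) / (v_sample + v_buffer)`.
#' For the standard 5 nM / 100 uL loading in a 400 uL insert this is 1.25 nM.
#'
#' @inheritParams compute_b
#' @param geometry A [dialysis_geometry()].
#' @return Tt in nM, vectorized.
#' @examples
#' compute_tt(1.25, 1.25)   # equal concentrations: 1.25
#' @export
compute_tt <- function(conc_sample, conc_buffer,
                       geometry = dialysis_geometry()) {
  stopifnot(inherits(geometry, "dialysis_geometry"))
  (conc_sample * geometry$v_sample + conc_buffer * geometry$v_buffer) /
    geometry$v_total
}

#' Percent inhibition of tracer binding
#'
#' `100 * (1 - bound_I / bound_I0)` where `bound_I0` is the bound tracer
#' concentration without inhibitor. Values outside `[0, 100]` (measurement
#' noise) are clamped with a warning.
#'
#' @param bound_I Bound tracer concentration at an inhibitor level (nM).
#' @param bound_I0 Bound tracer concentration without inhibitor (nM, > 0).
#' @return Percent inhibition in `[0, 100]`.
#' @examples
#' percent_inhibition(0.41, 0.82)  # 50
#' @export
percent_inhibition <- function(bound_I, bound_I0) {
  if (any(bound_I0 <= 0, na.rm = TRUE)) {
    rlang::abort("bound_I0 must be > 0", class = "dialyzr_invalid")
  }
  p <- 100 * (1 - bound_I / bound_I0)
  if (any(p < 0 | p > 100, na.rm = TRUE)) {
    rlang::warn("percent inhibition clamped to [0, 100]")
    p <- pmin(pmax(p, 0), 100)
  }
  p
}

#' Build an inhibition curve from per-level summaries
#'
#' @param level_nM Inhibitor levels (nM, strictly increasing).
#' @param pct_inhibition Mean percent inhibition per level.
#' @param sd Standard deviation per level (default 0).
#' @param n Replicates per level (default 1).
#' @param scale Reporting scale of the levels.
#' @param bound_I0 Zero-inhibitor bound tracer concentration (nM), optional.
#' @return A tibble of class `inhibition_curve`.
#' @examples
#' inhibition_curve(c(0, 10, 100), c(0, 40, 60))
#' @export
inhibition_curve <- function(level_nM, pct_inhibition, sd = 0, n = 1L,
                             scale = c("buffer-initial", "total-volume"),
                             bound_I0 = NA_real_) {
  scale <- match.arg(scale)
  stopifnot(length(level_nM) == length(pct_inhibition))
  if (is.unsorted(level_nM, strictly = TRUE)) {
    rlang::abort("levels must be strictly increasing",
                 class = "dialyzr_invalid")
  }
  if (any(n < 1)) rlang::abort("n must be >= 1", class = "dialyzr_invalid")
  out <- tibble::tibble(level_nM = level_nM,
                        pct_inhibition = pct_inhibition,
                        sd = rep_len(sd, length(level_nM)),
                        n = rep_len(as.integer(n), length(level_nM)))
  class(out) <- c("inhibition_curve", class(out))
  attr(out, "scale") <- scale
  attr(out, "bound_I0") <- bound_I0
  out
}

#' Interpolate the 50 % inhibition concentration (I50)
#'
#' Finds the first ascending crossing of 50 % inhibition and interpolates
#' linearly in `log10(level)` between the bracketing pair (titrations are
#' log-spaced, and percent inhibition is near-linear in log concentration
#' around the midpoint). A point at exactly 50 % returns that level.
#'
#' @param curve An [inhibition_curve()] (the zero level, if present, anchors
#'   0 % inhibition but is excluded from the log-scale interpolation grid).
#' @return I50 in nM.
#' @examples
#' interpolate_i50(inhibition_curve(c(10, 100), c(40, 60)))  # 31.62
#' @export
interpolate_i50 <- function(curve) {
  stopifnot(inherits(curve, "inhibition_curve"))
  pos <- curve[curve$level_nM > 0, ]
  x <- pos$level_nM
  y <- pos$pct_inhibition
  exact <- which(y == 50)
  if (length(exact) > 0) return(x[exact[1]])
  cross <- which(y[-length(y)] < 50 & y[-1] > 50)
  if (length(cross) == 0) {
    rlang::abort("inhibition curve does not cross 50 %: I50 not reached",
                 class = "dialyzr_i50_error")
  }
  j <- cross[1]
  lx <- log10(x[j]) + (50 - y[j]) / (y[j + 1] - y[j]) *
    (log10(x[j + 1]) - log10(x[j]))
  10^lx
}

#' Classify binding strength from bound percentages at two dilutions
#'
#' Applies the 5 % rules: *no binding* when < 5 % of the tracer is bound at a
#' 1:25 serum dilution; *low affinity* when > 5 % is bound at 1:25 but < 5 %
#' at 1:400; *quantifiable* otherwise.
#'
#' @param pct_bound_1_25 Percent tracer bound at 1:25 dilution.
#' @param pct_bound_1_400 Percent tracer bound at 1:400 dilution (may be `NA`
#'   when the 1:25 value is already below threshold).
#' @param threshold Classification threshold in percent (default 5).
#' @return One of `"no_binding"`, `"low_affinity"`, `"quantifiable"`.
#' @examples
#' classify_binding(61.5, 3)    # low_affinity
#' classify_binding(3, NA)      # no_binding
#' classify_binding(61.5, 45)   # quantifiable
#' @export
classify_binding <- function(pct_bound_1_25, pct_bound_1_400,
                             threshold = 5) {
  stopifnot(is.numeric(pct_bound_1_25), length(pct_bound_1_25) == 1)
  if (pct_bound_1_25 < threshold) return("no_binding")
  if (!is.na(pct_bound_1_400) && pct_bound_1_400 < threshold) {
    return("low_affinity")
  }
  "quantifiable"
}

#' Drug stability QC gate
#'
#' Pass when at least `threshold` of the drug survives the incubation;
#' conditions failing the gate cannot support a trustworthy Kd (the analyte
#' mixture changes during equilibration).
#'
#' @param remaining_24h Fraction remaining in `[0, 1]`.
#' @param threshold Pass threshold (default 0.90).
#' @return `"pass"` or `"fail"`.
#' @examples
#' stability_gate(0.799)  # heroin in buffer: fail
#' stability_gate(1.0)    # pass
#' @export
stability_gate <- function(remaining_24h, threshold = 0.90) {
  stopifnot(is.numeric(remaining_24h), length(remaining_24h) == 1,
            remaining_24h >= 0, remaining_24h <= 1)
  if (remaining_24h >= threshold) "pass" else "fail"
}
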