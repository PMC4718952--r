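# End-to-end Kd estimation from a tidy measured dataset.

#' Estimate the apparent dissociation constant from a measured dataset
#'
#' Runs the full competition-dialysis pipeline on a replicate-level measured
#' dataset (as produced by [generate_dataset()] or read with
#' [read_measured_dataset()]): bound fraction `b` and total tracer
#' concentration `Tt` from the zero-inhibitor condition, percent inhibition
#' per titration level, I50 by log-linear interpolation, and the Mueller
#' equation `Kd = (I50 - Tt) * (1 - 1.5 b + 0.5 b^2)`. QC gates flag `b`
#' outside the valid estimation window (default 0.4-0.7; the Kd is still
#' computed but flagged, as affinity tables conventionally report all
#' conditions) and analyte instability over the incubation. When the curve
#' never crosses 50 %, the result is classified instead of quantified.
#'
#' @param data A `measured_dataset` tibble (columns `condition_id`,
#'   `inhibitor_level_nM`, `chamber`, `analyte`, `replicate`, `conc_nM`,
#'   `dilution`, `esterase_inhibitors`). Negative-control conditions are
#'   identified by `condition_id` matching `negative_pattern`.
#' @param geometry A [dialysis_geometry()] (taken from the attached design
#'   when present).
#' @param scale Reporting scale of `inhibitor_level_nM` (from the attached
#'   design when present); stored on the result.
#' @param method `"per-replicate"` (default): b, I50 and Kd are computed per
#'   replicate triple and summarized as mean and SD. `"pooled"`: replicate
#'   concentrations are averaged first and a single estimate is computed.
#' @param tracer Tracer analyte name; `NULL` auto-detects the analyte present
#'   in the zero-inhibitor test condition.
#' @param b_window Valid `b` window for the Mueller estimate, default
#'   `c(0.4, 0.7)`.
#' @param stability_threshold Minimum fraction of analyte remaining over the
#'   incubation for the stability gate (default 0.90).
#' @param classification_threshold Bound-percent threshold for the binding
#'   classification (default 5).
#' @param incubation_h Incubation time used for the stability gate (from the
#'   attached design when present, else 24).
#' @param degradation A [degradation_model()] for the stability gate.
#' @param negative_pattern Regex identifying negative-control conditions.
#' @return An object of class `kd_estimate`; see [tidy.kd_estimate()].
#' @examples
#' d <- generate_dataset(assay_design(site_conc = 3, tracer_kd = 2,
#'                                    inhibitor_kd = 2, seed = 7))
#' est <- estimate_kd(d)
#' est
#' tidy(est)
#' @export
estimate_kd <- function(data,
                        geometry = NULL,
                        scale = NULL,
                        method = c("per-replicate", "pooled"),
                        tracer = NULL,
                        b_window = c(0.4, 0.7),
                        stability_threshold = 0.90,
                        classification_threshold = 5,
                        incubation_h = NULL,
                        degradation = degradation_model(),
                        negative_pattern = "^neg") {
  method <- match.arg(method)
  .check_dataset(data)
  design <- attr(data, "design")
  if (is.null(geometry)) {
    geometry <- if (!is.null(design)) design$geometry else dialysis_geometry()
  }
  if (is.null(scale)) {
    scale <- if (!is.null(design)) design$scale else "buffer-initial"
  }
  scale <- match.arg(scale, c("buffer-initial", "total-volume"))
  if (is.null(incubation_h)) {
    incubation_h <- if (!is.null(design)) design$incubation_h else 24
  }

  is_neg <- grepl(negative_pattern, data$condition_id)
  test <- data[!is_neg, ]
  zero <- test[test$inhibitor_level_nM == 0, ]
  if (nrow(zero) == 0) {
    rlang::abort("dataset has no zero-inhibitor test condition",
                 class = "dialyzr_invalid")
  }
  if (is.null(tracer)) tracer <- unique(zero$analyte)[1]

  wide <- function(d) {
    d <- d[d$analyte == tracer, c("condition_id", "inhibitor_level_nM",
                                  "chamber", "replicate", "conc_nM")]
    tidyr::pivot_wider(d, names_from = "chamber", values_from = "conc_nM")
  }

  z <- wide(zero)
  z$b <- compute_b(z$sample, z$buffer)
  z$tt <- compute_tt(z$sample, z$buffer, geometry)
  z$bound0 <- pmax(z$sample - z$buffer, 0)

  tit <- wide(test[test$inhibitor_level_nM > 0, ])
  tit <- dplyr::arrange(tit, .data$inhibitor_level_nM, .data$replicate)
  tit <- dplyr::left_join(tit, z[, c("replicate", "bound0")],
                          by = "replicate")
  tit$bound <- pmax(tit$sample - tit$buffer, 0)
  # replicates with no measurable zero-inhibitor binding cannot express
  # percent inhibition (negative controls, no-binding sera)
  tit <- tit[tit$bound0 > 0, ]
  any_binding <- nrow(tit) > 0
  if (any_binding) {
    tit$pct_inhibition <- percent_inhibition(tit$bound, tit$bound0)
    curve_tbl <- dplyr::summarise(
      dplyr::group_by(tit, .data$inhibitor_level_nM),
      mean_pct = mean(.data$pct_inhibition),
      sd = stats::sd(.data$pct_inhibition),
      n = dplyr::n(), .groups = "drop")
    curve <- inhibition_curve(curve_tbl$inhibitor_level_nM,
                              curve_tbl$mean_pct,
                              sd = ifelse(is.na(curve_tbl$sd), 0,
                                          curve_tbl$sd),
                              n = curve_tbl$n, scale = scale,
                              bound_I0 = mean(z$bound0))
  } else {
    curve <- NULL
  }

  try_i50 <- function(lv, pct) {
    tryCatch(interpolate_i50(inhibition_curve(lv, pct, scale = scale)),
             dialyzr_i50_error = function(e) NA_real_)
  }

  if (method == "per-replicate") {
    per_rep <- purrr::map_dfr(sort(unique(z$replicate)), function(r) {
      d <- tit[tit$replicate == r, ]
      zr <- z[z$replicate == r, ]
      i50 <- if (nrow(d) == 0) NA_real_ else
        try_i50(d$inhibitor_level_nM, d$pct_inhibition)
      kd <- if (is.na(i50)) NA_real_ else {
        suppressWarnings(muller_kd(i50, zr$tt, zr$b))
      }
      tibble::tibble(replicate = r, b = zr$b, tt = zr$tt, i50 = i50, kd = kd)
    })
    b_mean <- mean(per_rep$b); b_sd <- stats::sd(per_rep$b)
    tt_mean <- mean(per_rep$tt)
    i50_mean <- mean(per_rep$i50)
    i50_sd <- stats::sd(per_rep$i50)
    kd_mean <- mean(per_rep$kd)
    kd_sd <- stats::sd(per_rep$kd)
  } else {
    per_rep <- NULL
    b_mean <- mean(z$b); b_sd <- stats::sd(z$b)
    tt_mean <- mean(z$tt)
    i50_mean <- if (is.null(curve)) NA_real_ else
      try_i50(curve$level_nM, curve$pct_inhibition)
    i50_sd <- NA_real_
    kd_mean <- if (is.na(i50_mean)) NA_real_ else {
      suppressWarnings(muller_kd(i50_mean, tt_mean, b_mean))
    }
    kd_sd <- NA_real_
  }

  # QC gates ----------------------------------------------------------------
  qc_b_window <- if (!is.na(b_mean) && b_mean >= b_window[1] &&
                     b_mean <= b_window[2]) "pass" else "fail"

  stab <- purrr::map_dbl(unique(test$analyte), function(a) {
    tryCatch(
      degradation_remaining(a, unique(test$dilution)[1],
                            isTRUE(unique(test$esterase_inhibitors)[1]),
                            incubation_h, degradation),
      dialyzr_invalid = function(e) NA_real_)
  })
  qc_stability <- if (all(is.na(stab))) {
    "pass"
  } else if (all(stab[!is.na(stab)] >= stability_threshold)) "pass" else "fail"

  # classification ----------------------------------------------------------
  pct_bound <- 100 * b_mean
  i50_reached <- !is.na(i50_mean) && (method == "pooled" ||
                                      !anyNA(per_rep$kd))
  dils <- unique(zero$dilution)
  classification <- if (pct_bound < classification_threshold) {
    "no_binding"
  } else if (i50_reached) {
    "quantifiable"
  } else if (any(dils <= 25)) {
    # bound at low dilution but I50 unreachable at the working dilution
    "low_affinity"
  } else {
    "not_determined"
  }
  if (classification != "quantifiable") {
    kd_mean <- NA_real_; kd_sd <- NA_real_
  }

  structure(
    list(b = b_mean, b_sd = b_sd,
         tt = tt_mean,
         i50 = i50_mean, i50_sd = i50_sd,
         correction = if (is.na(b_mean)) NA_real_ else
           correction_factor(min(max(b_mean, 0), 1)),
         kd = kd_mean, kd_sd = kd_sd,
         qc_b_window = qc_b_window,
         qc_stability = qc_stability,
         classification = classification,
         curve = curve,
         replicates = per_rep,
         method = method, scale = scale, tracer = tracer,
         b_window = b_window,
         n = if (is.null(per_rep)) length(unique(z$replicate))
             else nrow(per_rep)),
    class = "kd_estimate"
  )
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat("<kd_estimate>", x$tracer, sprintf("(%s, %s scale)\n",
                                         x$method, x$scale))
  fmt <- function(m, s) {
    if (is.na(m)) return("not determined")
    if (is.na(s)) sprintf("%.3g", m) else sprintf("%.3g +/- %.2g", m, s)
  }
  cat(sprintf("  b    : %s  [window %g-%g: %s]\n", fmt(x$b, x$b_sd),
              x$b_window[1], x$b_window[2], x$qc_b_window))
  cat(sprintf("  Tt   : %.4g nM\n", x$tt))
  cat(sprintf("  I50  : %s nM\n", fmt(x$i50, x$i50_sd)))
  cat(sprintf("  Kd   : %s nM\n", fmt(x$kd, x$kd_sd)))
  cat(sprintf("  QC stability: %s | classification: %s\n",
              x$qc_stability, x$classification))
  invisible(x)
}

#' Tidy a Kd estimate into a one-row tibble
#'
#' @param x A `kd_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate's main quantities
#'   (`b`, `b_sd`, `tt_nM`, `i50_nM`, `i50_sd`, `correction`, `kd_nM`,
#'   `kd_sd`, `qc_b_window`, `qc_stability`, `classification`).
#' @export
tidy.kd_estimate <- function(x, ...) {
  tibble::tibble(
    tracer = x$tracer,
    b = x$b, b_sd = x$b_sd,
    tt_nM = x$tt,
    i50_nM = x$i50, i50_sd = x$i50_sd,
    correction = x$correction,
    kd_nM = x$kd, kd_sd = x$kd_sd,
    qc_b_window = x$qc_b_window,
    qc_stability = x$qc_stability,
    classification = x$classification
  )
}

#' One-row model summary of a Kd estimate
#'
#' @param x A `kd_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `n` replicates, method, scale, QC flags.
#' @export
glance.kd_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method, scale = x$scale,
                 qc_b_window = x$qc_b_window, qc_stability = x$qc_stability,
                 classification = x$classification)
}

.check_dataset <- function(data) {
  need <- c("condition_id", "inhibitor_level_nM", "chamber", "analyte",
            "replicate", "conc_nM", "dilution", "esterase_inhibitors")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    rlang::abort(paste0("dataset is missing columns: ",
                        paste(miss, collapse = ", ")),
                 class = "dialyzr_invalid")
  }
  invisible(data)
}
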