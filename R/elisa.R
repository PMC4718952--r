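# Competition-ELISA side of the comparison: 4PL IC50 fitting, a
# phenomenological curve simulator, and the IC50-versus-Kd discrepancy report
# over the packaged reference tables.

# 4PL on log10 concentration; hill > 0 gives a decreasing (competition) curve
.fourpl <- function(lx, top, bottom, hill, lic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (lx - lic50)))
}

#' Fit a four-parameter logistic competition curve
#'
#' Least-squares 4PL fit of normalized response versus log10 inhibitor
#' concentration (the standard "log(inhibitor) vs. normalized response"
#' model); the IC50 is the inflection point on the concentration scale.
#' Initialization is deterministic: top/bottom from the response extremes,
#' IC50 from the level nearest half-range, Hill slope 1; the optimization is
#' bounded.
#'
#' @param data A data frame of measured points.
#' @param level,response Columns of `data` holding inhibitor concentration
#'   (uM, > 0) and normalized response (%); tidy-eval, defaults `level_uM`
#'   and `response_pct`.
#' @return An object of class `fourpl_fit` with elements `top`, `bottom`,
#'   `hill`, `ic50` (uM), `rss`, `converged`, `no_inhibition`, and the data
#'   used. When the response range is below 10 % the fit is skipped and
#'   flagged `no_inhibition` (no IC50).
#' @examples
#' d <- simulate_elisa_curve(ic50_true = 1, noise_cv = 0, seed = 1)
#' fit_4pl(d)
#' @export
fit_4pl <- function(data, level = level_uM, response = response_pct) {
  x <- dplyr::pull(data, {{ level }})
  y <- dplyr::pull(data, {{ response }})
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(x <= 0)) {
    rlang::abort("concentration levels must be > 0", class = "dialyzr_invalid")
  }
  if (length(unique(x)) < 5) {
    rlang::abort("need >= 5 concentration levels spanning the transition",
                 class = "dialyzr_invalid")
  }

  out <- list(data = tibble::tibble(level_uM = x, response_pct = y))
  if (diff(range(y)) < 10) {
    out <- c(out, list(top = max(y), bottom = min(y), hill = NA_real_,
                       ic50 = NA_real_, rss = NA_real_, converged = FALSE,
                       no_inhibition = TRUE))
    class(out) <- "fourpl_fit"
    return(out)
  }

  lx <- log10(x)
  half <- (max(y) + min(y)) / 2
  start <- c(top = max(y), bottom = min(y), hill = 1,
             lic50 = lx[which.min(abs(y - half))])
  span <- diff(range(y))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - .fourpl(lx, p["top"], p["bottom"], p["hill"],
                                 p["lic50"]),
    lower = c(top = min(y) - span, bottom = min(y) - span,
              hill = 0.1, lic50 = min(lx) - 2),
    upper = c(top = max(y) + span, bottom = max(y) + span,
              hill = 10, lic50 = max(lx) + 2),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- fit$par
  out <- c(out, list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                     hill = unname(cf["hill"]),
                     ic50 = unname(10^cf["lic50"]),
                     rss = fit$deviance,
                     converged = fit$info %in% 1:4,
                     no_inhibition = FALSE))
  class(out) <- "fourpl_fit"
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$no_inhibition) {
    cat("<fourpl_fit> flat response: no inhibition, IC50 not defined\n")
  } else {
    cat(sprintf("<fourpl_fit> IC50 %.4g uM | hill %.3g | top %.3g | bottom %.3g | rss %.3g\n",
                x$ic50, x$hill, x$top, x$bottom, x$rss))
  }
  invisible(x)
}

#' @rdname fit_4pl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("top", "bottom", "hill", "ic50"),
    estimate = c(x$top, x$bottom, x$hill, x$ic50)
  )
}

#' @rdname fit_4pl
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(ic50_uM = x$ic50, hill = x$hill, rss = x$rss,
                 converged = x$converged, no_inhibition = x$no_inhibition)
}

#' Simulate a competition-ELISA dilution series
#'
#' Phenomenological stand-in for plate data: noiseless 4PL responses at 8
#' half-log-spaced levels around a chosen true IC50, with multiplicative
#' lognormal replicate noise. The surface-avidity gap between plate IC50 and
#' solution Kd is not modeled mechanistically; `ic50_true` is an input.
#'
#' @param ic50_true True IC50 in uM (> 0).
#' @param hill Hill slope (default 1).
#' @param top,bottom Response plateaus in percent.
#' @param noise_cv Multiplicative CV of a measured response (default 0.02).
#' @param n_replicates Replicates per level (default 3).
#' @param levels Concentration levels (uM); default 8 half-log levels from
#'   `ic50_true / 100` to `ic50_true * 10^1.5`.
#' @param seed Integer seed or `NULL`.
#' @return A tibble with columns `level_uM`, `replicate`, `response_pct`.
#' @examples
#' simulate_elisa_curve(1.1, seed = 3)
#' @export
simulate_elisa_curve <- function(ic50_true, hill = 1, top = 100, bottom = 0,
                                 noise_cv = 0.02, n_replicates = 3,
                                 levels = NULL, seed = NULL) {
  stopifnot(is.numeric(ic50_true), length(ic50_true) == 1)
  if (ic50_true <= 0) {
    rlang::abort("ic50_true must be > 0", class = "dialyzr_invalid")
  }
  if (is.null(levels)) levels <- ic50_true * 10^seq(-2, 1.5, by = 0.5)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  grid <- tidyr::crossing(level_uM = levels,
                          replicate = seq_len(n_replicates))
  mu <- .fourpl(log10(grid$level_uM), top, bottom, hill, log10(ic50_true))
  grid$response_pct <- mu * .lnoise(nrow(grid), noise_cv)
  grid
}

#' IC50-versus-Kd discrepancy report
#'
#' Joins the packaged plate IC50 table with the dialysis Kd table and reports
#' the ratio `IC50 / Kd` (with uM converted to nM) for every serum-drug pair
#' where both are uncensored numbers. Pairs with a censored IC50 (reported
#' only as exceeding the tested range) or a classified (low-affinity /
#' no-binding) Kd entry are flagged `not_computable` and never given a
#' number.
#'
#' @param kd_table Tibble like [ed_serum_kd()]: columns `serum`, `drug`,
#'   `kd_nM`, `classification`.
#' @param ic50_table Tibble like [elisa_titer_ic50()]: columns `serum`,
#'   `drug`, `ic50_uM`, `censored`.
#' @return A tibble with one row per joined pair: `serum`, `drug`, `kd_nM`,
#'   `ic50_uM`, `censored`, `ratio` (IC50 in nM over Kd in nM) and `status`.
#' @examples
#' rep <- ic50_kd_ratio()
#' dplyr::filter(rep, status == "ok")
#' @export
ic50_kd_ratio <- function(kd_table = ed_serum_kd(),
                          ic50_table = elisa_titer_ic50()) {
  need_kd <- c("serum", "drug", "kd_nM", "classification")
  need_ic <- c("serum", "drug", "ic50_uM", "censored")
  if (!all(need_kd %in% names(kd_table)) ||
      !all(need_ic %in% names(ic50_table))) {
    rlang::abort("tables lack the required columns", class = "dialyzr_invalid")
  }
  joined <- dplyr::inner_join(
    kd_table[, need_kd], ic50_table[, need_ic],
    by = c("serum", "drug"))
  joined <- dplyr::mutate(
    joined,
    computable = !.data$censored & .data$classification == "quantifiable" &
      !is.na(.data$kd_nM) & !is.na(.data$ic50_uM),
    ratio = dplyr::if_else(.data$computable,
                           .data$ic50_uM * 1e3 / .data$kd_nM, NA_real_),
    status = dplyr::if_else(.data$computable, "ok", "not_computable")
  )
  dplyr::select(joined, "serum", "drug", "kd_nM", "ic50_uM", "censored",
                "classification", "ratio", "status")
}
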