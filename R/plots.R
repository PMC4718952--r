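# ggplot2 diagnostics for the main result types.

#' Plot an inhibition curve
#'
#' Percent inhibition versus inhibitor level on a log axis, with +/- SD error
#' bars where replicate scatter is available and a reference line at 50 %.
#'
#' @param object An [inhibition_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sys <- binding_system(2.4, tracer_ligand(kd_site = 2),
#'                       ligand("morphine", 2, 0, "buffer"))
#' autoplot(predict_inhibition_curve(sys, c(0, 10^seq(1, 5, 0.5))))
#' @export
autoplot.inhibition_curve <- function(object, ...) {
  d <- object[object$level_nM > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$level_nM,
                                       y = .data$pct_inhibition)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("inhibitor level (nM, %s scale)",
                              attr(object, "scale")),
                  y = "% inhibition of tracer binding")
  if (any(d$sd > 0)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct_inhibition - .data$sd,
                   ymax = .data$pct_inhibition + .data$sd), width = 0.05)
  }
  p
}

#' Plot a fitted 4PL competition curve
#'
#' Measured normalized responses with the fitted logistic overlaid and the
#' IC50 marked.
#'
#' @param object A [fit_4pl()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$level_uM,
                                       y = .data$response_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inhibitor (uM)", y = "normalized response (%)")
  if (!object$no_inhibition) {
    grid <- exp(seq(log(min(d$level_uM)), log(max(d$level_uM)),
                    length.out = 200))
    fitted <- tibble::tibble(
      level_uM = grid,
      response_pct = .fourpl(log10(grid), object$top, object$bottom,
                             object$hill, log10(object$ic50)))
    p <- p +
      ggplot2::geom_line(data = fitted, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed",
                          colour = "grey50")
  }
  p
}

#' Plot a dialysis equilibration time course
#'
#' Percent of each analyte in each chamber versus time: the signature of the
#' approach to equilibrium (a passive cassette relaxes to a 50/50
#' concentration split; antibody retains tracer in the sample chamber).
#'
#' @param timecourse Output of [simulate_timecourse()].
#' @return A ggplot object.
#' @examples
#' tc <- simulate_timecourse(binding_system(0, tracer_ligand()),
#'                           times = c(0, 1, 3, 6, 12, 24))
#' plot_timecourse(tc)
#' @export
plot_timecourse <- function(timecourse) {
  totals <- dplyr::summarise(
    dplyr::group_by(timecourse, .data$time_h, .data$analyte),
    total = sum(.data$conc_nM), .groups = "drop")
  d <- dplyr::left_join(timecourse, totals, by = c("time_h", "analyte"))
  d$pct <- 100 * d$conc_nM / d$total
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$pct,
                                  colour = .data$chamber,
                                  linetype = .data$analyte)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "% of analyte (concentration basis)")
}
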