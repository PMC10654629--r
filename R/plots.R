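#' Plot a cohort trace
#'
#' State occupancy (progression-free, progressed, dead) against time.
#'
#' @param object A `cohort_trace` from [build_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("pfs", "pd", "death"),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = c("pfs", "pd", "death"),
                       labels = c("Progression-free", "Progressed",
                                  "Dead"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle,
                                     y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Cycle (months)", y = "State occupancy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars spanning the INMB obtained at the low and high value of
#' each parameter, ordered by impact, with the base-case INMB as a
#' reference line.
#'
#' @param object An `owsa_result` from [owsa()] or [run_owsa()].
#' @param top Show only the `top` most influential parameters.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot owsa_result
#' @export
autoplot.owsa_result <- function(object, top = 12, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base_inmb <- attr(object, "base_inmb")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_at_low,
                                       xend = .data$inmb_at_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_inmb, linetype = 2) +
    ggplot2::labs(x = "Incremental net monetary benefit (USD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.owsa_result
#' @export
plot_tornado <- function(object, top = 12) autoplot(object, top = top)

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `ceac_curve` from [ceac()].
#' @param wtp Optional threshold to mark with a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, wtp = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$wtp,
                                    y = .data$probability_cost_effective)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp,
                                                  linetype = 2)
  p
}

#' @rdname autoplot.ceac_curve
#' @export
plot_ceac <- function(object, wtp = NULL) autoplot(object, wtp = wtp)

#' Cost-effectiveness plane of PSA draws
#'
#' Incremental cost against incremental QALYs, one point per Monte Carlo
#' draw, with the willingness-to-pay threshold as a line through the
#' origin.
#'
#' @param object A `psa_result` from [psa()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  wtp <- attr(object, "wtp")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$delta_qalys,
                               y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.psa_result
#' @export
plot_ce_plane <- function(object) autoplot(object)
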