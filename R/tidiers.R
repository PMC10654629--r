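#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cost-effectiveness comparison
#'
#' `tidy()` returns the per-arm discounted totals with the incremental
#' row statistics in the published table layout (one row per arm: cost,
#' incremental cost, effectiveness, incremental effectiveness, ICER,
#' INMB); `glance()` returns the one-row comparative summary.
#'
#' @param x A `ce_result` from [compare()] or [run_base_case()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ce_result
#' @export
tidy.ce_result <- function(x, ...) {
  tibble::tibble(
    arm = x$arms$arm,
    cost = x$arms$total_cost,
    incremental_cost = c(x$delta_cost, NA_real_),
    effectiveness_qalys = x$arms$total_qalys,
    incremental_effectiveness_qalys = c(x$delta_qalys, NA_real_),
    icer = c(x$icer, NA_real_),
    inmb = c(x$inmb, NA_real_)
  )
}

#' @rdname tidy.ce_result
#' @method glance ce_result
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost, delta_qalys = x$delta_qalys,
    icer = x$icer, inmb = x$inmb, wtp = x$wtp,
    cost_effective = x$cost_effective, dominance = x$dominance
  )
}

#' Tidy a Weibull maximum-likelihood fit
#'
#' `tidy()` gives one row per parameter with delta-method standard errors;
#' `glance()` gives fit-level statistics including the implied median and
#' mean survival.
#'
#' @param x A `weibull_fit` from [fit_weibull_mle()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("scale_lambda", "shape_gamma"),
    estimate = c(x$params$scale_lambda, x$params$shape_gamma),
    std.error = c(x$se[["scale_lambda"]], x$se[["shape_gamma"]])
  )
}

#' @rdname tidy.weibull_fit
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, logLik = x$loglik,
    median_survival = median_survival(x$params),
    mean_survival = mean_survival(x$params),
    converged = x$converged
  )
}

#' Summarise a probabilistic sensitivity analysis
#'
#' One-row summary of a [psa()] run: mean incremental cost and QALYs over
#' the draws, the ICER of those means, and the probability of
#' cost-effectiveness at the configured threshold.
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  wtp <- attr(x, "wtp")
  tibble::tibble(
    n_iter = attr(x, "n_iter"),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qalys = mean(x$delta_qalys),
    icer_of_means = mean(x$delta_cost) / mean(x$delta_qalys),
    wtp = wtp,
    probability_cost_effective = mean(x$inmb > 0)
  )
}
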