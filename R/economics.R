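#' Discount factor for a monthly cycle
#'
#' Annual-rate discounting applied continuously in cycle fractions of a
#' year: \eqn{(1 + r)^{-t/12}} for cycle `t`.
#'
#' @param cycle Cycle index (months), non-negative; vectorised.
#' @param annual_rate Annual discount rate, non-negative fraction.
#' @return Discount factors in (0, 1\].
#' @examples
#' discount_factor(c(0, 12, 120), 0.05)
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (annual_rate < 0) stop("`annual_rate` must be non-negative.",
                            call. = FALSE)
  if (any(cycle < 0)) stop("`cycle` must be non-negative.", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

#' Per-cycle cost profile of a treatment strategy
#'
#' Costs in USD per monthly cycle. The treatment-phase components (drug,
#' chemotherapy backbone, antiemetics, tests, adverse-event management,
#' hospitalization) accrue while the cohort occupies the progression-free
#' state; the subsequent-therapy cost accrues while in progressed disease.
#' A component may additionally carry a cycle-dependent multiplier schedule
#' (see [donation_schedule_cost()]).
#'
#' @param pfs_components Named non-negative numeric vector of per-cycle
#'   treatment-phase costs.
#' @param pd_cost Per-cycle cost in the progressed-disease state.
#' @param schedules Named list mapping a component name to a function
#'   `f(cycle) -> multiplier in [0, 1]`; components without an entry accrue
#'   at full cost every cycle.
#' @return A list of class `cost_profile`.
#' @examples
#' cost_profile(c(drug = 3415.47, chemotherapy = 705.15), pd_cost = 430.95)
#' @export
cost_profile <- function(pfs_components, pd_cost, schedules = list()) {
  if (is.null(names(pfs_components)) || any(names(pfs_components) == "")) {
    stop("`pfs_components` must be a named vector.", call. = FALSE)
  }
  if (any(pfs_components < 0) || pd_cost < 0) {
    stop("Costs must be non-negative.", call. = FALSE)
  }
  if (length(schedules) &&
      !all(names(schedules) %in% names(pfs_components))) {
    stop("Schedules must refer to existing components.", call. = FALSE)
  }
  structure(list(pfs_components = pfs_components,
                 pd_cost = as.numeric(pd_cost),
                 schedules = schedules),
            class = "cost_profile")
}

# Total treatment-phase cost at each cycle, applying any schedules.
# Cycle 0 (only weighted under half-cycle correction) uses the cycle-1
# multiplier so a schedule cannot act before treatment starts.
pfs_cost_at <- function(costs, cycles) {
  base <- sum(costs$pfs_components)
  out <- rep(base, length(cycles))
  for (comp in names(costs$schedules)) {
    mult <- vapply(pmax(cycles, 1), costs$schedules[[comp]], numeric(1))
    if (any(mult < 0 | mult > 1)) {
      stop("Schedule multipliers must lie in [0, 1].", call. = FALSE)
    }
    out <- out + costs$pfs_components[[comp]] * (mult - 1)
  }
  out
}

#' Health-state utilities
#'
#' @param pfs Utility while progression-free (default 0.68).
#' @param pd Utility after progression (default 0.42). Death is 0.
#' @return A list of class `utility_set`.
#' @export
utility_set <- function(pfs = 0.68, pd = 0.42) {
  if (!(pd >= 0 && pd <= pfs && pfs <= 1)) {
    stop("Utilities must satisfy 0 <= pd <= pfs <= 1.", call. = FALSE)
  }
  structure(list(pfs = pfs, pd = pd, death = 0), class = "utility_set")
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Sums state-occupancy-weighted per-cycle costs and utilities with annual
#' discounting. Utilities are annual-scale, so each monthly cycle
#' contributes occupancy x utility / 12 QALYs. Under the default
#' half-cycle correction the cycle-0 and terminal states get half weight
#' (trapezoidal accrual); without it, accrual runs over cycle-end states
#' 1..horizon.
#'
#' @param trace A [build_trace()] tibble.
#' @param costs A [cost_profile()].
#' @param utilities A [utility_set()].
#' @param settings A [model_settings()]; defaults to the settings the trace
#'   was built with, and must match its horizon.
#' @return A one-row tibble with `total_cost` (USD) and `total_qalys`.
#' @examples
#' tr <- build_trace(weibull_params(0.0594, 1.275),
#'                   weibull_params(0.0119, 1.478))
#' accrue(tr, cost_profile(c(drug = 3415.47), 430.95), utility_set())
#' @export
accrue <- function(trace, costs, utilities,
                   settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(costs, "cost_profile"),
            inherits(utilities, "utility_set"),
            inherits(settings, "model_settings"))
  h <- settings$horizon_cycles
  if (nrow(trace) != h + 1L) {
    stop("Trace horizon does not match `settings$horizon_cycles`.",
         call. = FALSE)
  }
  w <- if (settings$half_cycle_correction) {
    c(0.5, rep(1, h - 1L), 0.5)
  } else {
    c(0, rep(1, h))
  }
  disc <- discount_factor(trace$cycle, settings$discount_rate_annual)
  cost_t <- trace$pfs * pfs_cost_at(costs, trace$cycle) +
    trace$pd * costs$pd_cost
  qaly_t <- (trace$pfs * utilities$pfs + trace$pd * utilities$pd) / 12
  tibble::tibble(total_cost = sum(w * disc * cost_t),
                 total_qalys = sum(w * disc * qaly_t))
}

#' Compare two strategies: ICER, INMB and the cost-effectiveness decision
#'
#' Computes incremental cost and effectiveness (`arm_a - arm_b`), the
#' incremental cost-effectiveness ratio `ICER = dC / dE`, and the
#' incremental net monetary benefit `INMB = dE * WTP - dC`. A strategy is
#' deemed cost-effective at the threshold when `INMB > 0` (equivalently,
#' for `dE > 0`, when the ICER is below the WTP). Dominance (cheaper and
#' more effective, or dearer and less effective) is labelled.
#'
#' @param arm_a,arm_b Accrual results for the intervention and comparator:
#'   one-row tibbles from [accrue()], or anything with `total_cost` and
#'   `total_qalys`.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param labels Character vector of two strategy names.
#' @return An object of class `ce_result`; see [tidy.ce_result()] and
#'   [glance.ce_result()].
#' @examples
#' compare(list(total_cost = 43427.43, total_qalys = 0.78),
#'         list(total_cost = 13879.55, total_qalys = 0.62))
#' @export
compare <- function(arm_a, arm_b, wtp = 37663.26,
                    labels = c("intervention", "comparator")) {
  get <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || !is.finite(v)) stop("Arm is missing `", f, "`.",
                                          call. = FALSE)
    as.numeric(v)
  }
  ca <- get(arm_a, "total_cost"); qa <- get(arm_a, "total_qalys")
  cb <- get(arm_b, "total_cost"); qb <- get(arm_b, "total_qalys")
  dc <- ca - cb
  de <- qa - qb
  icer <- if (de != 0) dc / de else NA_real_
  inmb <- de * wtp - dc
  dominance <- if (de > 0 && dc < 0) {
    "intervention dominant"
  } else if (de < 0 && dc > 0) {
    "intervention dominated"
  } else {
    "none"
  }
  structure(list(
    arms = tibble::tibble(arm = labels, total_cost = c(ca, cb),
                          total_qalys = c(qa, qb)),
    delta_cost = dc, delta_qalys = de, icer = icer,
    icer_defined = de != 0, inmb = inmb, wtp = wtp,
    cost_effective = inmb > 0, dominance = dominance
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness comparison (WTP $", format(x$wtp, big.mark = ","),
      "/QALY)\n", sep = "")
  print(x$arms)
  cat(sprintf("  Incremental cost:  $%.2f\n", x$delta_cost))
  cat(sprintf("  Incremental QALYs: %.4f\n", x$delta_qalys))
  if (x$icer_defined) {
    cat(sprintf("  ICER:  $%.2f/QALY\n", x$icer))
  } else {
    cat("  ICER:  undefined (no QALY difference)\n")
  }
  cat(sprintf("  INMB:  $%.2f  ->  %scost-effective at threshold\n",
              x$inmb, if (x$cost_effective) "" else "NOT "))
  if (x$dominance != "none") cat("  Dominance:", x$dominance, "\n")
  invisible(x)
}

#' Apply a patient-assistance (drug donation) schedule to a cost profile
#'
#' Rescales one component's per-cycle cost by a cycle-dependent multiplier
#' in \[0, 1\], and zeroes it after `cap_cycles`. This expresses
#' pay-some-cycles / free-some-cycles assistance programmes (for
#' serplulimab: self-fund 600 mg, receive 600 mg free; self-fund another
#' 600 mg, then free until progression, capped at two years) as an explicit
#' cost schedule.
#'
#' @param costs A [cost_profile()].
#' @param multiplier A function `f(cycle) -> [0, 1]`, or a numeric vector
#'   of per-cycle multipliers (cycles beyond its length reuse the last
#'   value).
#' @param cap_cycles Cycle after which the component costs nothing.
#' @param component Which component the schedule applies to.
#' @return A new [cost_profile()].
#' @examples
#' base <- cost_profile(c(drug = 3415.47, chemotherapy = 705.15), 430.95)
#' donated <- donation_schedule_cost(base, rep(c(1, 0), each = 3), 24)
#' @export
donation_schedule_cost <- function(costs, multiplier, cap_cycles = 24,
                                   component = "drug") {
  stopifnot(inherits(costs, "cost_profile"))
  if (!component %in% names(costs$pfs_components)) {
    stop("Unknown component `", component, "`.", call. = FALSE)
  }
  if (is.numeric(multiplier)) {
    vec <- multiplier
    if (any(vec < 0 | vec > 1)) {
      stop("Multipliers must lie in [0, 1].", call. = FALSE)
    }
    mfun <- function(cycle) vec[pmin(ceiling(cycle), length(vec))]
  } else if (is.function(multiplier)) {
    mfun <- multiplier
  } else {
    stop("`multiplier` must be a function or numeric vector.",
         call. = FALSE)
  }
  probe <- vapply(seq_len(min(cap_cycles, 120)), mfun, numeric(1))
  if (any(probe < 0 | probe > 1)) {
    stop("Multipliers must lie in [0, 1].", call. = FALSE)
  }
  sched <- function(cycle) {
    m <- ifelse(cycle > cap_cycles, 0, mfun(cycle))
    if (any(m < 0 | m > 1)) {
      stop("Multipliers must lie in [0, 1].", call. = FALSE)
    }
    m
  }
  schedules <- costs$schedules
  schedules[[component]] <- sched
  cost_profile(costs$pfs_components, costs$pd_cost, schedules)
}
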