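#' Moment-matched gamma and beta sampling for parameter uncertainty
#'
#' Standard second-order parameterisations used in probabilistic
#' sensitivity analysis: a gamma with `shape = mean^2/se^2`,
#' `rate = mean/se^2` for costs, and a beta with
#' `alpha = mean * nu`, `beta = (1 - mean) * nu`,
#' `nu = mean(1 - mean)/se^2 - 1` for utilities. With `se = 0` the draws
#' are degenerate at the mean (no random numbers are consumed).
#'
#' @param n Number of draws.
#' @param mean Target mean (gamma: non-negative; beta: in (0, 1)).
#' @param se Target standard error, non-negative; for the beta it must
#'   satisfy `se^2 < mean * (1 - mean)`.
#' @return Numeric vector of `n` draws.
#' @examples
#' summary(sample_gamma(1000, 3415.47, 683.09))
#' @export
sample_gamma <- function(n, mean, se) {
  if (mean < 0 || se < 0) stop("`mean` and `se` must be non-negative.",
                               call. = FALSE)
  if (se == 0 || mean == 0) return(rep(mean, n))
  stats::rgamma(n, shape = mean^2 / se^2, rate = mean / se^2)
}

#' @rdname sample_gamma
#' @export
sample_beta <- function(n, mean, se) {
  if (mean <= 0 || mean >= 1) stop("`mean` must be in (0, 1).",
                                   call. = FALSE)
  if (se < 0) stop("`se` must be non-negative.", call. = FALSE)
  if (se == 0) return(rep(mean, n))
  if (se^2 >= mean * (1 - mean)) {
    stop("Infeasible beta moments: need se^2 < mean * (1 - mean).",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' One-way deterministic sensitivity analysis with tornado ranking
#'
#' Re-runs the full cohort model twice per parameter, at
#' `base * (1 - span)` and `base * (1 + span)` with everything else held at
#' baseline, and ranks parameters by the width of the induced INMB range
#' (the tornado order). Parameters are addressed by path:
#' `"<arm>.costs.<component>"` for a single cost component,
#' `"<arm>.pfs_cost_total"` for joint scaling of all treatment-phase
#' components of an arm (the "cost of PFS" tornado bar), and
#' `"utilities.pfs"` / `"utilities.pd"`. Arms are `intervention` and
#' `comparator`; the subsequent-therapy (progressed-state) cost component
#' is `"<arm>.costs.subsequent_therapy"`.
#'
#' @param config An analysis configuration (see [default_config()]).
#' @param population Population block to analyse.
#' @param parameters Character vector of parameter paths; default
#'   [owsa_default_parameters()].
#' @param span Fractional variation (default 0.20 for +/-20%).
#' @return A tibble of class `owsa_result`, one row per parameter, ordered
#'   by decreasing `range_width`; base-case ICER/INMB are attached as
#'   attributes `base_icer` / `base_inmb`.
#' @export
owsa <- function(config = default_config(), population = "cps_ge1",
                 parameters = NULL, span = 0.20) {
  validate_config(config)
  if (span < 0) stop("`span` must be non-negative.", call. = FALSE)
  if (is.null(parameters)) {
    parameters <- owsa_default_parameters(config, population)
  }
  if (!length(parameters)) {
    stop("`parameters` must name at least one parameter.", call. = FALSE)
  }
  base <- run_base_case(config, population)
  rows <- purrr::map_dfr(parameters, function(p) {
    base_value <- owsa_parameter_value(config, population, p)
    lo <- run_base_case(owsa_set(config, population, p, 1 - span),
                        population)
    hi <- run_base_case(owsa_set(config, population, p, 1 + span),
                        population)
    tibble::tibble(
      parameter = p,
      base_value = base_value,
      low_value = base_value * (1 - span),
      high_value = base_value * (1 + span),
      icer_at_low = lo$icer, icer_at_high = hi$icer,
      inmb_at_low = lo$inmb, inmb_at_high = hi$inmb,
      range_width = abs(hi$inmb - lo$inmb)
    )
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$range_width))
  attr(out, "base_icer") <- base$icer
  attr(out, "base_inmb") <- base$inmb
  attr(out, "population") <- population
  attr(out, "span") <- span
  class(out) <- c("owsa_result", class(out))
  out
}

#' Default one-way sensitivity parameter set
#'
#' Every cost component of both arms, the joint treatment-phase cost of
#' each arm, and both health-state utilities. Weibull survival parameters
#' are fixed, mirroring the published analysis.
#'
#' @inheritParams owsa
#' @return Character vector of parameter paths.
#' @export
owsa_default_parameters <- function(config = default_config(),
                                    population = "cps_ge1") {
  pop <- config$populations[[population]]
  if (is.null(pop)) stop("Unknown population `", population, "`.",
                         call. = FALSE)
  paths <- character(0)
  for (arm in c("intervention", "comparator")) {
    comps <- names(pop[[arm]]$costs)
    comps <- comps[!vapply(pop[[arm]]$costs, is.null, logical(1))]
    nonzero <- comps[vapply(comps, function(cc) {
      isTRUE(pop[[arm]]$costs[[cc]] > 0)
    }, logical(1))]
    paths <- c(paths, paste0(arm, ".costs.", nonzero),
               paste0(arm, ".pfs_cost_total"))
  }
  c(paths, "utilities.pfs", "utilities.pd")
}

# Baseline value a path refers to (total treatment-phase cost for the
# aggregate paths).
owsa_parameter_value <- function(config, population, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  pop <- config$populations[[population]]
  if (parts[1L] == "utilities") {
    v <- config$utilities[[parts[2L]]]
  } else if (length(parts) == 2L && parts[2L] == "pfs_cost_total") {
    costs <- pop[[parts[1L]]]$costs
    pfs_comps <- setdiff(names(costs), "subsequent_therapy")
    v <- sum(unlist(costs[pfs_comps]))
  } else if (length(parts) == 3L && parts[2L] == "costs") {
    v <- pop[[parts[1L]]]$costs[[parts[3L]]]
  } else {
    v <- NULL
  }
  if (is.null(v)) stop("Unknown parameter path `", path, "`.",
                       call. = FALSE)
  v
}

# Returns a config with the addressed parameter multiplied by `factor`.
owsa_set <- function(config, population, path, factor) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (parts[1L] == "utilities") {
    if (!parts[2L] %in% c("pfs", "pd")) {
      stop("Unknown parameter path `", path, "`.", call. = FALSE)
    }
    config$utilities[[parts[2L]]] <-
      min(config$utilities[[parts[2L]]] * factor, 1)
    return(config)
  }
  arm <- parts[1L]
  if (!arm %in% c("intervention", "comparator")) {
    stop("Unknown parameter path `", path, "`.", call. = FALSE)
  }
  costs <- config$populations[[population]][[arm]]$costs
  if (length(parts) == 2L && parts[2L] == "pfs_cost_total") {
    pfs_comps <- setdiff(names(costs), "subsequent_therapy")
    for (cc in pfs_comps) costs[[cc]] <- costs[[cc]] * factor
  } else if (length(parts) == 3L && parts[2L] == "costs" &&
             parts[3L] %in% names(costs)) {
    costs[[parts[3L]]] <- costs[[parts[3L]]] * factor
  } else {
    stop("Unknown parameter path `", path, "`.", call. = FALSE)
  }
  config$populations[[population]][[arm]]$costs <- costs
  config
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of all uncertain parameters at once: every
#' nonzero cost component is drawn from a moment-matched gamma and the two
#' health-state utilities from moment-matched betas (shared across arms
#' within a draw); Weibull survival parameters stay fixed at their point
#' estimates, as in the published analysis. Standard errors are
#' `se_fraction` of the mean (default 20%, matching the one-way
#' sensitivity span) since the source analysis reports none. Each draw is
#' a full model evaluation on the fixed cohort traces.
#'
#' @inheritParams owsa
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param se_fraction Standard error as a fraction of each mean.
#' @return A tibble of class `psa_result` with one row per draw: sampled
#'   parameters, per-arm discounted cost and QALYs, `delta_cost`,
#'   `delta_qalys`, `inmb`. Metadata (`n_iter`, `seed`, `wtp`,
#'   `population`, `se_fraction`) are attached as attributes.
#' @export
psa <- function(config = default_config(), population = "cps_ge1",
                n_iter = 1000, seed = NULL, se_fraction = 0.2) {
  validate_config(config)
  if (n_iter < 1) stop("`n_iter` must be at least 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  settings <- config_settings(config)
  pop <- config$populations[[population]]
  if (is.null(pop)) stop("Unknown population `", population, "`.",
                         call. = FALSE)

  draw_costs <- function(arm_name) {
    costs <- pop[[arm_name]]$costs
    comps <- names(costs)
    draws <- lapply(comps, function(cc) {
      m <- costs[[cc]]
      sample_gamma(n_iter, m, se_fraction * m)
    })
    names(draws) <- paste0(substr(arm_name, 1, 3), "_", comps)
    draws
  }
  # Fixed sampling order: intervention costs, comparator costs, utilities.
  d_int <- draw_costs("intervention")
  d_cmp <- draw_costs("comparator")
  u_pfs <- sample_beta(n_iter, config$utilities$pfs,
                       se_fraction * config$utilities$pfs)
  u_pd <- sample_beta(n_iter, config$utilities$pd,
                      se_fraction * config$utilities$pd)
  u_pd <- pmin(u_pd, u_pfs)  # keep the ordering constraint draw-wise

  arm_accrual <- function(arm_name, comp_draws) {
    strat <- build_strategy(pop[[arm_name]])
    trace <- build_trace(strat$pfs, strat$os, settings)
    h <- settings$horizon_cycles
    w <- if (settings$half_cycle_correction) c(0.5, rep(1, h - 1L), 0.5)
         else c(0, rep(1, h))
    disc <- discount_factor(trace$cycle, settings$discount_rate_annual)
    a_pfs <- sum(w * disc * trace$pfs)  # discounted PFS cycle-occupancy
    a_pd <- sum(w * disc * trace$pd)
    comps <- names(pop[[arm_name]]$costs)
    pfs_comps <- setdiff(comps, "subsequent_therapy")
    pre <- paste0(substr(arm_name, 1, 3), "_")
    comp_mat <- do.call(cbind, comp_draws[paste0(pre, pfs_comps)])
    cost <- rowSums(comp_mat) * a_pfs +
      comp_draws[[paste0(pre, "subsequent_therapy")]] * a_pd
    qalys <- (a_pfs * u_pfs + a_pd * u_pd) / 12
    list(cost = cost, qalys = qalys)
  }
  acc_int <- arm_accrual("intervention", d_int)
  acc_cmp <- arm_accrual("comparator", d_cmp)

  out <- tibble::as_tibble(c(
    list(draw = seq_len(n_iter)), d_int, d_cmp,
    list(u_pfs = u_pfs, u_pd = u_pd,
         cost_intervention = acc_int$cost,
         qalys_intervention = acc_int$qalys,
         cost_comparator = acc_cmp$cost,
         qalys_comparator = acc_cmp$qalys)
  ))
  out$delta_cost <- out$cost_intervention - out$cost_comparator
  out$delta_qalys <- out$qalys_intervention - out$qalys_comparator
  out$inmb <- out$delta_qalys * settings$wtp_per_qaly - out$delta_cost
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  attr(out, "wtp") <- settings$wtp_per_qaly
  attr(out, "population") <- population
  attr(out, "se_fraction") <- se_fraction
  class(out) <- c("psa_result", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the intervention has positive incremental net monetary benefit.
#'
#' @param psa_result A [psa()] tibble.
#' @param wtp_grid Vector of WTP thresholds; the default spans $0 to
#'   $250,000 in $2,500 steps.
#' @return A tibble of class `ceac_curve` with columns `wtp` and
#'   `probability_cost_effective`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 250000, by = 2500)) {
  stopifnot(inherits(psa_result, "psa_result"))
  if (!length(wtp_grid)) stop("`wtp_grid` must be non-empty.",
                              call. = FALSE)
  probs <- vapply(wtp_grid, function(w) {
    mean(psa_result$delta_qalys * w - psa_result$delta_cost > 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = wtp_grid,
                        probability_cost_effective = probs)
  class(out) <- c("ceac_curve", class(out))
  out
}
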