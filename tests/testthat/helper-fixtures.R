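# Published base-case curves for the PD-L1 CPS>=1 population.
combo_pfs <- function() weibull_params(0.0594, 1.275)
combo_os <- function() weibull_params(0.0119, 1.478)
chemo_pfs <- function() weibull_params(0.0595, 1.532)
chemo_os <- function() weibull_params(0.0158, 1.482)

combo_costs <- function() {
  cost_profile(
    c(drug = 3415.47, chemotherapy = 705.15, antiemetics = 200.16,
      tests = 384.63, adverse_events = 50.13, hospitalization = 40.34),
    pd_cost = 430.95
  )
}

chemo_costs <- function() {
  cost_profile(
    c(chemotherapy = 578.75, antiemetics = 164.28, tests = 330.37,
      adverse_events = 40.86, hospitalization = 33.11),
    pd_cost = 869.24
  )
}

# Median by bisection on the survival function itself, independent of the
# closed form.
median_by_bisection <- function(params, tol = 1e-10) {
  lo <- 0; hi <- 1
  while (weibull_survival(params, hi) > 0.5) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (weibull_survival(params, mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# One-arm Weibull sample with optional administrative censoring, bypassing
# the coupled trial simulator (independent generation for fit oracles).
rweibull_ipd <- function(n, params, censor_time = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (-log(runif(n)) / params$scale_lambda)^(1 / params$shape_gamma)
  pseudo_ipd(pmin(t, censor_time), as.numeric(t <= censor_time))
}
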