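test_that("discount factors follow the annual-rate closed form", {
  expect_identical(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(12, 0.05), 1 / 1.05)
  expect_equal(discount_factor(120, 0), 1)
  expect_true(all(diff(discount_factor(0:120, 0.05)) < 0))
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("accrual is zero for zero costs and utilities", {
  tr <- build_trace(combo_pfs(), combo_os())
  res <- accrue(tr, cost_profile(c(drug = 0), 0), utility_set(0, 0))
  expect_equal(res$total_cost, 0)
  expect_equal(res$total_qalys, 0)
})

test_that("undiscounted life-years match restricted mean survival", {
  # full utilities, zero discounting: QALYs = restricted mean OS (years)
  settings <- model_settings(discount_rate_annual = 0,
                             half_cycle_correction = TRUE)
  tr <- build_trace(combo_pfs(), combo_os(), settings)
  res <- accrue(tr, cost_profile(c(drug = 0), 0), utility_set(1, 1),
                settings)
  rmst <- stats::integrate(function(t) weibull_survival(combo_os(), t),
                           0, 120, rel.tol = 1e-10)$value
  expect_equal(res$total_qalys, rmst / 12, tolerance = 1e-3)
})

test_that("horizon mismatches are caught", {
  tr <- build_trace(combo_pfs(), combo_os(),
                    model_settings(horizon_cycles = 60))
  expect_error(
    accrue(tr, combo_costs(), utility_set(), model_settings()),
    "horizon")
})

test_that("comparative statistics follow the ICER and INMB formulas", {
  res <- compare(list(total_cost = 43427.43, total_qalys = 0.78),
                 list(total_cost = 13879.55, total_qalys = 0.62),
                 wtp = 37663.26)
  expect_equal(res$delta_cost, 29547.88)
  expect_equal(res$delta_qalys, 0.16)
  expect_equal(res$icer, 184674.25)
  expect_equal(res$inmb, 0.16 * 37663.26 - 29547.88)
  expect_false(res$cost_effective)
  # degenerate effectiveness difference
  tie <- compare(list(total_cost = 100, total_qalys = 0.5),
                 list(total_cost = 40, total_qalys = 0.5))
  expect_true(is.na(tie$icer))
  expect_false(tie$icer_defined)
  expect_equal(tie$inmb, -60)
  # dominance labels
  dom <- compare(list(total_cost = 10, total_qalys = 1),
                 list(total_cost = 20, total_qalys = 0.5))
  expect_equal(dom$dominance, "intervention dominant")
})

test_that("INMB > 0 if and only if ICER < WTP whenever QALYs are gained", {
  set.seed(21)
  for (i in 1:200) {
    a <- list(total_cost = runif(1, 0, 1e5), total_qalys = runif(1, 0, 2))
    b <- list(total_cost = runif(1, 0, 1e5), total_qalys = runif(1, 0, 2))
    wtp <- runif(1, 1e3, 3e5)
    res <- compare(a, b, wtp)
    if (res$delta_qalys > 0) {
      expect_equal(res$inmb > 0, res$icer < wtp)
    }
  }
})

test_that("cost monotonicity moves the ICER the expected way", {
  base <- run_base_case(population = "cps_ge1")
  cfg <- default_config()
  cfg$populations$cps_ge1$intervention$costs$drug <- 4000
  up <- run_base_case(cfg, "cps_ge1")
  expect_gt(up$icer, base$icer)
  cfg2 <- default_config()
  cfg2$utilities$pfs <- 0.75
  better <- run_base_case(cfg2, "cps_ge1")
  expect_lt(better$icer, base$icer)  # intervention gains more PFS time
})

test_that("donation schedules rescale only the drug component", {
  costs <- combo_costs()
  ident <- donation_schedule_cost(costs, function(t) rep(1, length(t)),
                                  cap_cycles = 1e6)
  tr <- build_trace(combo_pfs(), combo_os())
  u <- utility_set()
  expect_equal(accrue(tr, ident, u), accrue(tr, costs, u))

  zero <- donation_schedule_cost(costs, function(t) rep(0, length(t)),
                                 cap_cycles = 1e6)
  full <- accrue(tr, costs, u)
  none <- accrue(tr, zero, u)
  drug_share <- accrue(
    tr, cost_profile(c(drug = 3415.47), 0), utility_set(0, 0))
  expect_equal(full$total_cost - none$total_cost, drug_share$total_cost,
               tolerance = 1e-9)
  expect_equal(full$total_qalys, none$total_qalys)

  expect_error(donation_schedule_cost(costs, function(t) t * 0 - 0.5),
               "\\[0, 1\\]")
})

test_that("the assistance-programme scenario lowers the ICER", {
  # pay 3 cycles / free 3 cycles / pay 3 / free until progression, <= 2 y
  sched <- c(1, 1, 1, 0, 0, 0, 1, 1, 1, rep(0, 15))
  cfg <- default_config()
  base <- run_base_case(cfg, "cps_ge1")
  donated <- donation_schedule_cost(combo_costs(), sched, cap_cycles = 24)
  settings <- model_settings()
  tr_i <- build_trace(combo_pfs(), combo_os(), settings)
  tr_c <- build_trace(chemo_pfs(), chemo_os(), settings)
  u <- utility_set()
  res <- compare(accrue(tr_i, donated, u), accrue(tr_c, chemo_costs(), u))
  expect_lt(res$icer, base$icer)
  expect_gt(res$icer, res$wtp)  # still above the threshold
})
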