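test_that("moment-matched gamma and beta draws hit their targets", {
  set.seed(31)
  g <- sample_gamma(1e5, 3415.47, 683.094)
  expect_equal(mean(g), 3415.47, tolerance = 0.01)
  expect_equal(stats::sd(g), 683.094, tolerance = 0.02)
  expect_true(all(g > 0))

  b <- sample_beta(1e5, 0.68, 0.136)
  expect_true(all(b > 0 & b < 1))
  expect_equal(mean(b), 0.68, tolerance = 0.01)
  expect_equal(stats::sd(b), 0.136, tolerance = 0.02)

  expect_identical(sample_gamma(5, 100, 0), rep(100, 5))
  expect_identical(sample_beta(5, 0.68, 0), rep(0.68, 5))
  expect_error(sample_beta(5, 0.5, 0.6), "Infeasible")
})

test_that("a zero span collapses the tornado to the base case", {
  res <- owsa(population = "cps_ge1",
              parameters = c("intervention.costs.drug", "utilities.pfs"),
              span = 0)
  expect_equal(res$icer_at_low, res$icer_at_high)
  expect_equal(res$icer_at_low, rep(attr(res, "base_icer"), 2))
  expect_equal(res$range_width, c(0, 0))
})

test_that("the tornado ranks the intervention PFS-phase cost first", {
  res <- run_owsa(population = "cps_ge1")
  expect_s3_class(res, "owsa_result")
  expect_equal(res$parameter[1], "intervention.pfs_cost_total")
  top6 <- res$parameter[1:6]
  expect_true("intervention.costs.drug" %in% top6)
  expect_true("utilities.pfs" %in% top6)
  expect_true(all(diff(res$range_width) <= 1e-9))
})

test_that("cost directions differ by arm, utilities by gradient", {
  res <- owsa(population = "cps_ge1",
              parameters = c("intervention.costs.chemotherapy",
                             "comparator.costs.chemotherapy"))
  int_row <- res[res$parameter == "intervention.costs.chemotherapy", ]
  cmp_row <- res[res$parameter == "comparator.costs.chemotherapy", ]
  # raising an intervention cost lowers INMB; raising a comparator cost
  # raises it
  expect_lt(int_row$inmb_at_high, int_row$inmb_at_low)
  expect_gt(cmp_row$inmb_at_high, cmp_row$inmb_at_low)
})

test_that("unknown parameter paths and empty lists are rejected", {
  expect_error(owsa(parameters = "intervention.costs.nonexistent"),
               "Unknown parameter path")
  expect_error(owsa(parameters = character(0)), "at least one")
})

test_that("the PSA is reproducible and degenerates correctly", {
  a <- psa(population = "cps_ge1", n_iter = 50, seed = 99)
  b <- psa(population = "cps_ge1", n_iter = 50, seed = 99)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_equal(nrow(a), 50)

  degen <- psa(population = "cps_ge1", n_iter = 5, seed = 1,
               se_fraction = 0)
  base <- run_base_case(population = "cps_ge1")
  expect_equal(degen$delta_cost, rep(base$delta_cost, 5),
               tolerance = 1e-9)
  expect_equal(degen$delta_qalys, rep(base$delta_qalys, 5),
               tolerance = 1e-9)
})

test_that("PSA draws respect support constraints and gain QALYs", {
  draws <- psa(population = "cps_ge1", n_iter = 500, seed = 7)
  expect_true(all(draws$u_pfs > 0 & draws$u_pfs < 1))
  expect_true(all(draws$u_pd <= draws$u_pfs))
  cost_cols <- grep("^(int|com)_", names(draws), value = TRUE)
  expect_true(all(as.matrix(draws[cost_cols]) >= 0))
  # survival curves are fixed and the intervention occupies more state
  # time, so every draw gains QALYs
  expect_true(all(draws$delta_qalys > 0))
})

test_that("PSA parameter means converge to their base values", {
  draws <- psa(population = "cps_ge1", n_iter = 1e5, seed = 13)
  expect_equal(mean(draws$int_drug), 3415.47,
               tolerance = 0.01)
  expect_equal(mean(draws$com_subsequent_therapy), 869.24,
               tolerance = 0.01)
  expect_equal(mean(draws$u_pfs), 0.68, tolerance = 0.01)
})

test_that("the CEAC has the right limits and is monotone", {
  draws <- psa(population = "cps_ge1", n_iter = 200, seed = 5)
  curve <- ceac(draws, wtp_grid = c(0, 37663.26, 1e5, 2e5, 1e7))
  expect_true(all(curve$probability_cost_effective >= 0 &
                    curve$probability_cost_effective <= 1))
  # all draws cost more, so nothing is acceptable at WTP 0
  expect_equal(curve$probability_cost_effective[1], 0)
  # far beyond any draw's ICER everything is acceptable
  expect_equal(curve$probability_cost_effective[5], 1)
  expect_true(!is.unsorted(curve$probability_cost_effective))
})
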