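test_that("exact step curves invert to the implied event times", {
  km <- digitized_km(c(2, 4), c(0.5, 0), n_total = 4)
  ipd <- reconstruct_ipd(km)
  expect_s3_class(ipd, "pseudo_ipd")
  expect_equal(nrow(ipd), 4)
  expect_equal(sort(ipd$time), c(2, 2, 4, 4))
  expect_true(all(ipd$event == 1))
  expect_lt(attr(ipd, "km_error"), 1e-12)
})

test_that("a terminal plateau becomes administrative censoring", {
  km <- digitized_km(c(2, 5, 15), c(0.7, 0.3, 0.3), n_total = 100)
  ipd <- reconstruct_ipd(km)
  expect_equal(nrow(ipd), 100)
  expect_equal(sum(ipd$event == 0 & ipd$time == 15), 30)
  expect_equal(sum(ipd$event), 70)
})

test_that("reconstruction validates its inputs", {
  expect_error(digitized_km(c(2, 4), c(0.5, 0.8), n_total = 10),
               "non-increasing")
  expect_error(digitized_km(c(4, 2), c(0.8, 0.5), n_total = 10),
               "strictly increasing")
  km <- digitized_km(1:5, c(0.8, 0.6, 0.4, 0.2, 0), n_total = 100)
  expect_error(reconstruct_ipd(km, target_n = 3), "infeasible")
})

test_that("KM of reconstructed records reproduces the digitized curve", {
  wos <- combo_os()
  spec <- trial_sim_spec(
    n_per_arm = c(a = 300, b = 2),
    pfs_params = list(a = combo_pfs(), b = combo_pfs()),
    os_params = list(a = wos, b = wos),
    admin_censor_time = 15, seed = 401)
  trial <- simulate_trial(spec)
  for (ep in c("pfs", "os")) {
    km <- km_estimate(ipd_from_trial(trial, "a", ep))
    rec <- reconstruct_ipd(km)
    expect_equal(nrow(rec), 300)
    expect_lt(attr(rec, "km_error"), 0.02)
  }
})

test_that("risk tables steer censoring into the right intervals", {
  # drops spread over follow-up with interior censoring visible in the
  # at-risk counts; reconstruction should place censorings inside the
  # intervals, not all at the end
  ipd0 <- rweibull_ipd(200, combo_os(), censor_time = Inf, seed = 77)
  # impose random in-study censoring
  set.seed(78)
  cens <- runif(200, 0, 40)
  ipd <- pseudo_ipd(pmin(ipd0$time, cens),
                    as.numeric(ipd0$time <= cens))
  km <- km_estimate(ipd, risk_times = seq(0, 40, by = 8))
  rec <- reconstruct_ipd(km)
  expect_equal(nrow(rec), 200)
  expect_lt(attr(rec, "km_error"), 0.02)
  # some censoring must occur strictly before the end of follow-up
  expect_gt(sum(rec$event == 0 & rec$time < max(km$time) - 1e-9), 0)
})

test_that("the Weibull MLE recovers simulated parameters", {
  truth <- weibull_params(0.06, 1.3)
  fit <- fit_weibull_mle(rweibull_ipd(2000, truth, seed = 402))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$scale_lambda - 0.06), 0.01)
  expect_lt(abs(fit$params$shape_gamma - 1.3), 0.1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(td$std.error > 0))
})

test_that("the MLE is consistent: bias shrinks with sample size", {
  truth <- weibull_params(0.06, 1.3)
  err <- vapply(c(200, 2000), function(n) {
    # average over a few replicates at fixed seeds
    fits <- vapply(1:5, function(i) {
      f <- fit_weibull_mle(rweibull_ipd(n, truth, seed = 500 + 7 * i + n))
      abs(f$params$shape_gamma - 1.3)
    }, numeric(1))
    mean(fits)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("censored data are handled and match an independent fitter", {
  truth <- weibull_params(0.0119, 1.478)
  ipd <- rweibull_ipd(2000, truth, censor_time = 24, seed = 403)
  expect_gt(mean(ipd$event == 0), 0.2)  # ~30% administrative censoring
  fit <- fit_weibull_mle(ipd)
  expect_lt(abs(fit$params$scale_lambda - 0.0119),
            2 * fit$se[["scale_lambda"]])
  expect_lt(abs(fit$params$shape_gamma - 1.478),
            2 * fit$se[["shape_gamma"]])
  # cross-check against flexsurv's Weibull AFT fit (different
  # parameterisation: lambda = scale^-shape)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(time, event) ~ 1, data = as.data.frame(ipd),
    dist = "weibull")
  shape_fs <- unname(fs$res["shape", "est"])
  lambda_fs <- unname(fs$res["scale", "est"])^(-shape_fs)
  expect_equal(fit$params$shape_gamma, shape_fs, tolerance = 1e-4)
  expect_equal(fit$params$scale_lambda, lambda_fs, tolerance = 1e-4)
})

test_that("fixed-shape fits reduce to the exponential MLE", {
  ipd <- rweibull_ipd(500, weibull_params(0.08, 1), censor_time = 20,
                      seed = 404)
  fit <- fit_weibull_mle(ipd, fix_shape = 1)
  expect_equal(fit$params$scale_lambda, sum(ipd$event) / sum(ipd$time),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_weibull_mle(pseudo_ipd(c(1, 2, 3), c(0, 0, 0))),
               "censored")
  expect_error(fit_weibull_mle(pseudo_ipd(c(1, 2, 3), c(1, 0, 0))),
               "two events")
})
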