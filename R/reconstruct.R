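#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Inverts a digitized Kaplan-Meier curve into approximate patient-level
#' event and censoring times, in the interval style used for published
#' curve-to-IPD reconstruction: within each interval between numbers-at-risk
#' times, events are allocated so the recomputed product-limit curve tracks
#' the digitized survival drops, and censorings are spread uniformly so the
#' at-risk count at the next risk-table time is honoured. Without a risk
#' table, all censoring is assumed administrative at the end of follow-up
#' (so a terminal plateau becomes censored records).
#'
#' @param km A [digitized_km()] curve.
#' @param target_n Number of records to reconstruct; defaults to the curve's
#'   `n_total`.
#'
#' @return A [pseudo_ipd()] tibble with `target_n` rows. The sup-norm error
#'   of the recomputed KM at the input time points is attached as attribute
#'   `km_error`.
#' @examples
#' km <- digitized_km(c(2, 4), c(0.5, 0), n_total = 4)
#' reconstruct_ipd(km)
#' @export
reconstruct_ipd <- function(km, target_n = attr(km, "n_total")) {
  stopifnot(inherits(km, "digitized_km"))
  if (length(target_n) != 1L || target_n < 1) {
    stop("`target_n` must be a positive integer.", call. = FALSE)
  }
  n_drops <- sum(diff(c(1, km$survival)) < -1e-12)
  if (target_n < n_drops) {
    stop("`target_n` is smaller than the number of survival drops; ",
         "reconstruction infeasible.", call. = FALSE)
  }
  risk <- attr(km, "risk_table")
  if (is.null(risk) || nrow(risk) < 2L) {
    rec <- reconstruct_simple(km, target_n)
  } else {
    rec <- reconstruct_with_risk_table(km, target_n, risk)
  }
  out <- pseudo_ipd(rec$time, rec$event)
  chk <- km_estimate(out)
  attr(out, "km_error") <- max(abs(km_survival_at(chk, km$time) -
                                     km$survival))
  out
}

# No risk table: events matched to drops, all censoring at final follow-up.
reconstruct_simple <- function(km, target_n) {
  n_risk <- target_n
  s_hat <- 1
  times <- numeric(0)
  events <- numeric(0)
  for (i in seq_along(km$time)) {
    if (n_risk == 0L) break
    d <- round(n_risk * (1 - km$survival[i] / s_hat))
    d <- min(max(d, 0), n_risk)
    if (d > 0) {
      times <- c(times, rep(km$time[i], d))
      events <- c(events, rep(1, d))
      s_hat <- s_hat * (1 - d / n_risk)
      n_risk <- n_risk - d
    }
  }
  if (n_risk > 0) {
    times <- c(times, rep(max(km$time), n_risk))
    events <- c(events, rep(0, n_risk))
  }
  list(time = times, event = events)
}

# Interval form: iteratively choose per-interval censor counts so the
# reconstructed at-risk count matches the published risk table.
reconstruct_with_risk_table <- function(km, target_n, risk) {
  rt_times <- risk$time
  rt_n <- round(risk$n_risk * target_n / max(risk$n_risk))
  follow_up <- max(km$time, rt_times)
  if (rt_times[length(rt_times)] < follow_up) {
    rt_times <- c(rt_times, follow_up)
    rt_n <- c(rt_n, NA_real_)  # unconstrained final boundary
  }
  n_int <- length(rt_times) - 1L
  cens_counts <- rep(0L, n_int)

  run <- function(cens_counts) {
    n_risk <- target_n
    s_hat <- 1
    times <- numeric(0)
    events <- numeric(0)
    boundary_n <- numeric(n_int)
    for (j in seq_len(n_int)) {
      lo <- rt_times[j]; hi <- rt_times[j + 1L]
      in_int <- which(km$time > lo & km$time <= hi)
      cj <- cens_counts[j]
      cens_t <- if (cj > 0) lo + (seq_len(cj) - 0.5) / cj * (hi - lo)
                else numeric(0)
      marks <- rbind(
        if (length(in_int))
          data.frame(t = km$time[in_int], s = km$survival[in_int], ev = 1),
        if (cj > 0) data.frame(t = cens_t, s = NA_real_, ev = 0)
      )
      if (!is.null(marks) && nrow(marks)) {
        marks <- marks[order(marks$t, -marks$ev), , drop = FALSE]
        for (k in seq_len(nrow(marks))) {
          if (marks$ev[k] == 0) {
            if (n_risk > 0) {
              times <- c(times, marks$t[k]); events <- c(events, 0)
              n_risk <- n_risk - 1L
            }
          } else {
            if (n_risk == 0L) next
            d <- round(n_risk * (1 - marks$s[k] / s_hat))
            d <- min(max(d, 0), n_risk)
            if (d > 0) {
              times <- c(times, rep(marks$t[k], d))
              events <- c(events, rep(1, d))
              s_hat <- s_hat * (1 - d / n_risk)
              n_risk <- n_risk - d
            }
          }
        }
      }
      boundary_n[j] <- n_risk
    }
    list(time = times, event = events, boundary_n = boundary_n,
         n_left = n_risk)
  }

  for (iter in 1:25) {
    res <- run(cens_counts)
    target_bound <- rt_n[-1L]
    adj <- ifelse(is.na(target_bound), 0, res$boundary_n - target_bound)
    new_counts <- pmax(cens_counts + adj, 0L)
    if (all(new_counts == cens_counts)) break
    cens_counts <- new_counts
  }
  res <- run(cens_counts)
  if (res$n_left > 0) {
    res$time <- c(res$time, rep(follow_up, res$n_left))
    res$event <- c(res$event, rep(0, res$n_left))
  }
  res
}

#' Maximum-likelihood Weibull fit to right-censored records
#'
#' Maximises the right-censored Weibull log-likelihood
#' \deqn{\ell(\lambda,\gamma)=\sum_{events}\log(\lambda\gamma t^{\gamma-1})
#'       -\sum_{all}\lambda t^{\gamma},}
#' in `(log lambda, log gamma)` space so the optimisation is unconstrained
#' and scale-stable. Starting values come from a least-squares fit of
#' `log(-log S)` against `log t` on the Kaplan-Meier curve of the input.
#' Standard errors are delta-method transforms of the inverse observed
#' information.
#'
#' @param ipd A [pseudo_ipd()] tibble; at least two events (one if the shape
#'   is fixed).
#' @param fix_shape Optional fixed value for the shape \eqn{\gamma}; with
#'   `fix_shape = 1` the fit reduces to the exponential MLE
#'   \eqn{\hat\lambda = events / \sum t}.
#'
#' @return An object of class `weibull_fit` with elements `params`
#'   ([weibull_params()]), `se` (named, natural scale), `vcov_log`,
#'   `loglik`, `n`, `n_events`, `converged`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_weibull_mle <- function(ipd, fix_shape = NULL) {
  ipd <- as_pseudo_ipd(ipd)
  t <- ipd$time
  d <- ipd$event
  n_ev <- sum(d)
  if (n_ev == 0) stop("All records are censored; cannot fit.", call. = FALSE)

  if (!is.null(fix_shape)) {
    stopifnot(fix_shape > 0)
    lam <- n_ev / sum(t^fix_shape)
    ll <- n_ev * (log(lam) + log(fix_shape)) +
      (fix_shape - 1) * sum(d * log(t)) - lam * sum(t^fix_shape)
    return(structure(list(
      params = weibull_params(lam, fix_shape),
      se = c(scale_lambda = lam / sqrt(n_ev), shape_gamma = 0),
      vcov_log = matrix(1 / n_ev, 1, 1,
                        dimnames = list("log_lambda", "log_lambda")),
      loglik = ll, n = length(t), n_events = n_ev, converged = TRUE
    ), class = "weibull_fit"))
  }
  if (n_ev < 2) stop("At least two events are required.", call. = FALSE)

  km <- km_estimate(ipd)
  usable <- km$survival > 0 & km$survival < 1 & km$time > 0
  if (sum(usable) >= 2) {
    cf <- stats::coef(stats::lm(log(-log(km$survival[usable])) ~
                                  log(km$time[usable])))
    start <- c(log_lambda = unname(cf[1L]),
               log_gamma = log(max(unname(cf[2L]), 0.05)))
  } else {
    start <- c(log_lambda = log(n_ev / sum(t)), log_gamma = 0)
  }

  nll <- function(par) {
    lam <- exp(par[1L]); gam <- exp(par[2L])
    -(n_ev * (log(lam) + log(gam)) + (gam - 1) * sum(d * log(t)) -
        lam * sum(t^gam))
  }
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  lam <- exp(unname(opt$par[1L])); gam <- exp(unname(opt$par[2L]))
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  dimnames(vc) <- list(c("log_lambda", "log_gamma"),
                       c("log_lambda", "log_gamma"))
  se <- c(scale_lambda = lam * sqrt(vc[1L, 1L]),
          shape_gamma = gam * sqrt(vc[2L, 2L]))
  structure(list(
    params = weibull_params(lam, gam), se = se, vcov_log = vc,
    loglik = -opt$value, n = length(t), n_events = n_ev,
    converged = opt$convergence == 0
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Right-censored Weibull maximum-likelihood fit\n")
  cat(sprintf("  n = %d (%d events), logLik = %.3f%s\n", x$n, x$n_events,
              x$loglik, if (x$converged) "" else " [not converged]"))
  cat(sprintf("  lambda = %.5f (se %.5f), gamma = %.4f (se %.4f)\n",
              x$params$scale_lambda, x$se[["scale_lambda"]],
              x$params$shape_gamma, x$se[["shape_gamma"]]))
  invisible(x)
}
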