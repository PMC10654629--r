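#' Digitized Kaplan-Meier curve
#'
#' A tibble of `(time, survival)` coordinates read off a published
#' Kaplan-Meier plot (or produced by [km_estimate()] /
#' [make_digitized_fixture()]), with the total starting cohort size and an
#' optional numbers-at-risk table attached as attributes.
#'
#' @param time Months since randomisation; strictly increasing, non-negative.
#' @param survival Survival probabilities; non-increasing, in \[0, 1\].
#' @param n_total Number of subjects the curve starts with.
#' @param risk_table Optional data frame with columns `time` and `n_risk`.
#'
#' @return A tibble of class `digitized_km` with columns `time` and
#'   `survival`; attributes `n_total` and `risk_table`.
#' @examples
#' digitized_km(c(2, 4), c(0.5, 0), n_total = 4)
#' @export
digitized_km <- function(time, survival, n_total, risk_table = NULL) {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) != length(survival) || length(time) == 0L) {
    stop("`time` and `survival` must be non-empty and of equal length.",
         call. = FALSE)
  }
  if (any(time < 0) || is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be non-negative and strictly increasing.",
         call. = FALSE)
  }
  if (survival[1L] > 1 || any(survival < 0) ||
      any(diff(survival) > 1e-12)) {
    stop("`survival` must start at or below 1 and be non-increasing.",
         call. = FALSE)
  }
  if (length(n_total) != 1L || n_total < 1 || n_total != round(n_total)) {
    stop("`n_total` must be a single positive integer.", call. = FALSE)
  }
  if (!is.null(risk_table)) {
    stopifnot(all(c("time", "n_risk") %in% names(risk_table)))
    risk_table <- tibble::as_tibble(risk_table[c("time", "n_risk")])
    if (any(risk_table$n_risk < 0)) {
      stop("Numbers at risk must be non-negative.", call. = FALSE)
    }
    risk_table <- dplyr::arrange(risk_table, .data$time)
  }
  out <- tibble::tibble(time = time, survival = survival)
  attr(out, "n_total") <- as.integer(n_total)
  attr(out, "risk_table") <- risk_table
  class(out) <- c("digitized_km", class(out))
  out
}

#' Pseudo individual patient data
#'
#' Event/censoring records reconstructed from a digitized Kaplan-Meier curve
#' or drawn by the trial simulator: one row per subject with a follow-up
#' `time` in months and an `event` indicator (1 = event, 0 = censored).
#'
#' @param time Positive follow-up times in months.
#' @param event Indicators, 1 for an observed event and 0 for censoring.
#' @return A tibble of class `pseudo_ipd` with columns `time` and `event`.
#' @examples
#' pseudo_ipd(c(2, 2, 4, 4), c(1, 1, 1, 1))
#' @export
pseudo_ipd <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) == 0L || length(time) != length(event)) {
    stop("`time` and `event` must be non-empty and of equal length.",
         call. = FALSE)
  }
  if (any(time <= 0)) stop("All follow-up times must be positive.",
                           call. = FALSE)
  if (!all(event %in% c(0, 1))) {
    stop("`event` must contain only 0 (censored) and 1 (event).",
         call. = FALSE)
  }
  out <- tibble::tibble(time = time, event = event)
  class(out) <- c("pseudo_ipd", class(out))
  out
}

as_pseudo_ipd <- function(x) {
  if (inherits(x, "pseudo_ipd")) return(x)
  if (is.data.frame(x) && all(c("time", "event") %in% names(x))) {
    return(pseudo_ipd(x$time, x$event))
  }
  stop("Expected a data frame with `time` and `event` columns.",
       call. = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve from patient-level records.
#' The returned curve has one point per distinct event time plus a terminal
#' point at the end of follow-up (so a plateau created by censoring is
#' represented), and a numbers-at-risk table evaluated at `risk_times`.
#'
#' @param ipd A [pseudo_ipd()] tibble (or data frame with `time`, `event`).
#' @param risk_times Times at which to tabulate numbers at risk; defaults to
#'   an even grid from 0 to the end of follow-up.
#'
#' @return A [digitized_km()] object.
#' @examples
#' km_estimate(pseudo_ipd(1:4, rep(1, 4)))
#' @export
km_estimate <- function(ipd, risk_times = NULL) {
  ipd <- as_pseudo_ipd(ipd)
  ord <- order(ipd$time, -ipd$event)
  time <- ipd$time[ord]
  event <- ipd$event[ord]
  n <- length(time)

  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    at_risk <- sum(time >= ev_times[i])
    d <- sum(time == ev_times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  follow_up <- max(time)
  if (length(ev_times) == 0L || ev_times[length(ev_times)] < follow_up) {
    ev_times <- c(ev_times, follow_up)
    surv <- c(surv, s)
  }
  if (is.null(risk_times)) {
    risk_times <- seq(0, ceiling(follow_up), length.out = 7L)
  }
  risk_table <- tibble::tibble(
    time = risk_times,
    n_risk = vapply(risk_times, function(tt) sum(time >= tt), numeric(1))
  )
  digitized_km(ev_times, pmax(surv, 0), n_total = n, risk_table = risk_table)
}

#' Emulate graphical digitization of a Kaplan-Meier curve
#'
#' Samples coordinates from a step curve the way a plot digitizer would:
#' `n_points` time points spread over follow-up, survival read with a small
#' symmetric error, clamped to \[0, 1\] and forced non-increasing by a
#' running minimum. The starting cohort size and risk table are carried
#' through unchanged.
#'
#' @param km A [digitized_km()] curve (typically from [km_estimate()]).
#' @param n_points Number of digitized points (>= 2).
#' @param noise_sd Standard deviation of the reading error, in survival
#'   units; 0.005 approximates careful plot extraction.
#' @param seed Optional integer seed for reproducible noise.
#'
#' @return A [digitized_km()] object with `n_points` rows.
#' @export
make_digitized_fixture <- function(km, n_points = 50, noise_sd = 0.005,
                                   seed = NULL) {
  stopifnot(inherits(km, "digitized_km"))
  if (n_points < 2) stop("`n_points` must be at least 2.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_max <- max(km$time)
  grid <- seq(t_max / n_points, t_max, length.out = n_points)
  surv <- km_survival_at(km, grid)
  if (noise_sd > 0) {
    surv <- surv + stats::rnorm(n_points, 0, noise_sd)
  }
  surv <- cummin(pmin(pmax(surv, 0), 1))
  digitized_km(grid, surv, n_total = attr(km, "n_total"),
               risk_table = attr(km, "risk_table"))
}

# Step-function lookup: survival just after time t (right-continuous),
# 1 before the first recorded point.
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Read and write digitized Kaplan-Meier curves as CSV
#'
#' The curve file has columns `time,survival`; the optional companion risk
#' table file has columns `time,n_risk`.
#'
#' @param path CSV file with `time` and `survival` columns.
#' @param n_total Starting cohort size of the digitized curve.
#' @param risk_table_path Optional CSV with `time` and `n_risk` columns.
#' @return `read_digitized_km()` returns a [digitized_km()] object;
#'   the writers return their input invisibly.
#' @export
read_digitized_km <- function(path, n_total, risk_table_path = NULL) {
  pts <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time", "survival") %in% names(pts)))
  risk <- NULL
  if (!is.null(risk_table_path)) {
    risk <- readr::read_csv(risk_table_path, show_col_types = FALSE)
  }
  digitized_km(pts$time, pts$survival, n_total = n_total, risk_table = risk)
}

#' @rdname read_digitized_km
#' @param km A [digitized_km()] object.
#' @export
write_digitized_km <- function(km, path, risk_table_path = NULL) {
  readr::write_csv(tibble::tibble(time = km$time, survival = km$survival),
                   path)
  rt <- attr(km, "risk_table")
  if (!is.null(risk_table_path) && !is.null(rt)) {
    readr::write_csv(rt, risk_table_path)
  }
  invisible(km)
}

#' @rdname read_digitized_km
#' @export
read_pseudo_ipd <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  pseudo_ipd(x$time, x$event)
}

#' @rdname read_digitized_km
#' @param ipd A [pseudo_ipd()] object.
#' @export
write_pseudo_ipd <- function(ipd, path) {
  readr::write_csv(tibble::tibble(time = ipd$time, event = ipd$event), path)
  invisible(ipd)
}
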