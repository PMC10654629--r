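#' Analysis configuration
#'
#' The whole analysis is driven by one structured configuration: global
#' model settings, health-state utilities, and per-population blocks
#' (`cps_ge1`, `cps_1to10`, `cps_ge10` for the PD-L1 combined positive
#' score strata) each holding an `intervention` and a `comparator` strategy
#' with per-cycle cost components and Weibull PFS/OS parameters, plus
#' one-way and probabilistic sensitivity-analysis blocks.
#' `default_config()` ships the published parameter set (serplulimab +
#' chemotherapy vs chemotherapy, costs in USD converted at $1 = 6.77 yuan,
#' utilities 0.68/0.42).
#'
#' @return A nested list of class `analysis_config`.
#' @examples
#' cfg <- default_config()
#' names(cfg$populations)
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml",
                          package = "esccea"))
}

#' @rdname default_config
#' @param path Path to a YAML configuration file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path,
                               call. = FALSE)
  config <- yaml::read_yaml(path)
  class(config) <- c("analysis_config", class(config))
  validate_config(config)
  config
}

#' @rdname default_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  fail <- function(path, msg) {
    stop("Invalid config at `", path, "`: ", msg, call. = FALSE)
  }
  need <- function(x, fields, where) {
    missing <- setdiff(fields, names(x))
    if (length(missing)) fail(where, paste("missing field(s)",
                                           paste(missing, collapse = ", ")))
  }
  need(config, c("settings", "utilities", "populations"), "(top level)")
  s <- config$settings
  need(s, c("horizon_cycles", "discount_rate_annual", "wtp_per_qaly"),
       "settings")
  if (s$horizon_cycles < 1) fail("settings.horizon_cycles",
                                 "must be >= 1")
  if (s$discount_rate_annual < 0 || s$discount_rate_annual >= 1) {
    fail("settings.discount_rate_annual", "must be in [0, 1)")
  }
  if (s$wtp_per_qaly <= 0) fail("settings.wtp_per_qaly",
                                "must be positive")
  u <- config$utilities
  need(u, c("pfs", "pd"), "utilities")
  if (!(u$pd >= 0 && u$pd <= u$pfs && u$pfs <= 1)) {
    fail("utilities", "need 0 <= pd <= pfs <= 1")
  }
  if (!length(config$populations)) fail("populations", "none defined")
  for (pn in names(config$populations)) {
    pop <- config$populations[[pn]]
    need(pop, c("intervention", "comparator"), paste0("populations.", pn))
    for (arm in c("intervention", "comparator")) {
      where <- paste0("populations.", pn, ".", arm)
      blk <- pop[[arm]]
      need(blk, c("costs", "pfs", "os"), where)
      need(blk$costs, "subsequent_therapy", paste0(where, ".costs"))
      if (any(unlist(blk$costs) < 0)) fail(paste0(where, ".costs"),
                                           "negative cost")
      for (curve in c("pfs", "os")) {
        cw <- paste0(where, ".", curve)
        need(blk[[curve]], c("scale_lambda", "shape_gamma"), cw)
        if (blk[[curve]]$scale_lambda <= 0 ||
            blk[[curve]]$shape_gamma <= 0) {
          fail(cw, "Weibull parameters must be positive")
        }
      }
    }
  }
  invisible(config)
}

# Settings object from the config block.
config_settings <- function(config) {
  s <- config$settings
  model_settings(
    cycle_length = s$cycle_length %||% 1,
    horizon_cycles = s$horizon_cycles,
    discount_rate_annual = s$discount_rate_annual,
    wtp_per_qaly = s$wtp_per_qaly,
    half_cycle_correction = s$half_cycle_correction %||% TRUE
  )
}

# Strategy (cost profile + curves) from one arm block of a population.
build_strategy <- function(arm_block) {
  costs <- arm_block$costs
  pfs_comps <- setdiff(names(costs), "subsequent_therapy")
  list(
    name = arm_block$name %||% "strategy",
    costs = cost_profile(
      pfs_components = unlist(costs[pfs_comps]),
      pd_cost = costs$subsequent_therapy
    ),
    pfs = weibull_params(arm_block$pfs$scale_lambda,
                         arm_block$pfs$shape_gamma),
    os = weibull_params(arm_block$os$scale_lambda,
                        arm_block$os$shape_gamma)
  )
}

#' Run the base-case cost-effectiveness analysis
#'
#' Builds both arms' cohort traces from the configured Weibull curves,
#' accrues discounted costs and QALYs, and compares them at the configured
#' willingness-to-pay threshold. With `output_dir` set, writes a CSV
#' report in the published table layout plus a run-metadata file.
#'
#' @param config An [default_config()]-style configuration.
#' @param population One of the configured population names.
#' @param output_dir Optional directory for CSV output.
#' @return A `ce_result` (see [compare()]).
#' @examples
#' run_base_case(population = "cps_ge1")
#' @export
run_base_case <- function(config = default_config(),
                          population = "cps_ge1", output_dir = NULL) {
  validate_config(config)
  pop <- config$populations[[population]]
  if (is.null(pop)) stop("Unknown population `", population, "`.",
                         call. = FALSE)
  settings <- config_settings(config)
  utilities <- utility_set(config$utilities$pfs, config$utilities$pd)
  arm_res <- lapply(c("intervention", "comparator"), function(arm) {
    strat <- build_strategy(pop[[arm]])
    trace <- build_trace(strat$pfs, strat$os, settings)
    accrue(trace, strat$costs, utilities, settings)
  })
  res <- compare(arm_res[[1L]], arm_res[[2L]], settings$wtp_per_qaly,
                 labels = c(pop$intervention$name %||% "intervention",
                            pop$comparator$name %||% "comparator"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(res),
                     file.path(output_dir,
                               paste0("base_case_", population, ".csv")))
    write_run_metadata(config, output_dir, population, seed = NULL)
  }
  res
}

#' Run the one-way sensitivity analysis
#'
#' @inheritParams run_base_case
#' @param ... Passed to [owsa()] (`parameters`, `span`).
#' @return An `owsa_result` tibble (tornado-ordered).
#' @export
run_owsa <- function(config = default_config(), population = "cps_ge1",
                     output_dir = NULL, ...) {
  args <- list(...)
  span <- args$span %||% config$owsa$span %||% 0.20
  parameters <- args$parameters %||% config$owsa$parameters
  res <- owsa(config, population, parameters = parameters, span = span)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tibble::as_tibble(res),
                     file.path(output_dir,
                               paste0("tornado_", population, ".csv")))
    write_run_metadata(config, output_dir, population, seed = NULL)
  }
  res
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the Monte Carlo resampling, derives the cost-effectiveness
#' acceptability curve, and (optionally) writes draw-level,
#' cost-effectiveness-plane and CEAC CSVs plus run metadata.
#'
#' @inheritParams run_base_case
#' @param n_iter,seed,se_fraction Override the config's `psa` block.
#' @param wtp_grid WTP grid for the CEAC; default from the config.
#' @return A list with elements `psa` (a `psa_result`) and `ceac`
#'   (a `ceac_curve`).
#' @export
run_psa <- function(config = default_config(), population = "cps_ge1",
                    n_iter = NULL, seed = NULL, se_fraction = NULL,
                    wtp_grid = NULL, output_dir = NULL) {
  blk <- config$psa %||% list()
  n_iter <- n_iter %||% blk$iterations %||% 1000
  seed <- seed %||% blk$seed
  se_fraction <- se_fraction %||% blk$se_fraction %||% 0.2
  if (is.null(wtp_grid)) {
    g <- blk$wtp_grid
    wtp_grid <- if (!is.null(g)) seq(g$from, g$to, by = g$by)
                else seq(0, 250000, by = 2500)
  }
  draws <- psa(config, population, n_iter = n_iter, seed = seed,
               se_fraction = se_fraction)
  curve <- ceac(draws, wtp_grid)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      dplyr::select(tibble::as_tibble(draws), "draw", "delta_cost",
                    "delta_qalys", "inmb"),
      file.path(output_dir, paste0("psa_draws_", population, ".csv")))
    readr::write_csv(tibble::as_tibble(curve),
                     file.path(output_dir,
                               paste0("ceac_", population, ".csv")))
    write_run_metadata(config, output_dir, population, seed = seed)
  }
  list(psa = draws, ceac = curve)
}

# Seed, config hash and package version, for reproducibility audits.
write_run_metadata <- function(config, output_dir, population, seed) {
  meta <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("esccea"))),
    paste0("population: ", population),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("config_hash: ", rlang::hash(unclass(config))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  writeLines(meta, file.path(output_dir, "run_metadata.yaml"))
  invisible(meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
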