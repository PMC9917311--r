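#' Run a configured analysis pipeline
#'
#' Executes the analyses requested by a single declarative config (a YAML
#' file path or an equivalent nested list) in dependency order, writing CSV
#' tables and a JSON summary that embeds the fully resolved config and the
#' package version. The schema is validated before any computation; unknown
#' keys are rejected with the offending field named.
#'
#' Config blocks:
#' * `space`: `{M, viable_lo, viable_hi}`.
#' * `rates`: `birth`/`death`/`misseg`, each `{kind, ...params}` with kinds
#'   `constant` (`value`), `linear` (`slope, base, c_ref, chromosome, floor,
#'   ceil`), `sinusoidal` (`amplitude, base, p_peak, period, floor, ceil`) or
#'   `tabulated` (`file`, a 2-column CSV `state,rate`).
#' * `simulation`: `{t_max, qss_tol, dt_check, initial}` (optional).
#' * `analysis`: any of `simulate: true`, `gershgorin: true`,
#'   `critical_curve: {parameter, grid}`, `multichrom: {interval,
#'   n_chromosomes, beta}`, `ploidy_estimate: {file}`,
#'   `calibrate: {file, response}`.
#' * `output`: `{dir}`; `seed`: integer.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @param output_dir Overrides `output$dir` in the config.
#' @return Invisibly, a list of the computed results (also serialized under
#'   the output directory as `summary.json` plus per-analysis CSVs).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  out_dir <- output_dir %||% config$output$dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  space <- space_from_config(config$space)
  rates <- rates_from_config(config$rates)
  validate_rates(space, rates)
  results <- list()
  analysis <- config$analysis %||% list()

  if (isTRUE(analysis$gershgorin)) {
    gen <- build_generator(space, rates)
    results$gershgorin <- as.list(gershgorin_conditions(gen))
  }
  if (isTRUE(analysis$simulate) || is.list(analysis$simulate)) {
    sim_cfg <- config$simulation %||% list()
    gen <- build_generator(space, rates)
    qss <- simulate_to_qss(
      gen,
      qss_tol = sim_cfg$qss_tol %||% 0.001,
      t_max = sim_cfg$t_max %||% 1e4,
      dt_check = sim_cfg$dt_check %||% 10
    )
    traj <- tidy.qss_result(qss) |>
      tidyr::pivot_wider(names_from = "state", values_from = "proportion",
                         names_prefix = "p_")
    utils::write.csv(traj, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    results$simulate <- as.list(glance.qss_result(qss))
  }
  if (!is.null(analysis$critical_curve)) {
    cc_cfg <- analysis$critical_curve
    grid <- as.numeric(cc_cfg$grid)
    curve <- critical_curve(space, cc_cfg$parameter %||% "beta", grid,
                            b0 = cc_cfg$b0 %||% 0.05)
    utils::write.csv(curve, file.path(out_dir, "critical_curve.csv"),
                     row.names = FALSE)
    results$critical_curve <- list(
      file = "critical_curve.csv", n_points = nrow(curve),
      parameter = attr(curve, "parameter_name")
    )
  }
  if (!is.null(analysis$multichrom)) {
    mc <- analysis$multichrom
    results$multichrom <- list(
      critical_turnover = multichromosome_critical(
        as.numeric(mc$interval), beta = mc$beta,
        n_chromosomes = mc$n_chromosomes
      )
    )
  }
  if (!is.null(analysis$ploidy_estimate)) {
    expr <- tibble::as_tibble(utils::read.csv(analysis$ploidy_estimate$file))
    est <- estimate_ploidy(expr)
    utils::write.csv(tidy.ploidy_estimate(est),
                     file.path(out_dir, "ploidy.csv"), row.names = FALSE)
    results$ploidy_estimate <- as.list(glance.ploidy_estimate(est))
  }
  if (!is.null(analysis$calibrate)) {
    cal <- tibble::as_tibble(utils::read.csv(analysis$calibrate$file))
    fit <- fit_linear_calibration(
      cal, response_name = analysis$calibrate$response %||% "response")
    results$calibrate <- as.list(glance.calibration_model(fit))
  }

  summary <- list(
    package = "karyomie",
    version = as.character(utils::packageVersion("karyomie")),
    config = config,
    results = results
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

validate_config <- function(config) {
  if (!is.list(config)) rlang::abort("config must be a list or YAML file path")
  allowed <- c("space", "rates", "simulation", "analysis", "output", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")))
  }
  for (req in c("space", "rates")) {
    if (is.null(config[[req]])) {
      rlang::abort(sprintf("config is missing the required `%s` block", req))
    }
  }
  if (!is.null(config$analysis)) {
    ok <- c("simulate", "gershgorin", "critical_curve", "multichrom",
            "ploidy_estimate", "calibrate")
    unknown <- setdiff(names(config$analysis), ok)
    if (length(unknown)) {
      rlang::abort(paste0("unknown analysis field(s): ",
                          paste(unknown, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

rates_from_config <- function(block) {
  for (req in c("birth", "death", "misseg")) {
    if (is.null(block[[req]])) {
      rlang::abort(sprintf("rates config is missing the `%s` kernel", req))
    }
  }
  unknown <- setdiff(names(block), c("birth", "death", "misseg"))
  if (length(unknown)) {
    rlang::abort(paste0("unknown rates field(s): ",
                        paste(unknown, collapse = ", ")))
  }
  rate_model(kernel_from_config(block$birth, "birth"),
             kernel_from_config(block$death, "death"),
             kernel_from_config(block$misseg, "misseg"))
}

kernel_from_config <- function(k, field) {
  if (is.null(k$kind)) {
    rlang::abort(sprintf("rates.%s: missing `kind`", field))
  }
  switch(
    k$kind,
    constant = constant_kernel(k$value %||%
      rlang::abort(sprintf("rates.%s: constant kernel needs `value`", field))),
    linear = linear_kernel(k$slope, k$base, c_ref = k$c_ref %||% 2,
                           chromosome = k$chromosome %||% 1,
                           floor = k$floor %||% 0, ceil = k$ceil %||% Inf),
    sinusoidal = sinusoidal_kernel(k$amplitude, k$base,
                                   p_peak = k$p_peak %||% 66,
                                   period = k$period %||% 44,
                                   floor = k$floor %||% 0,
                                   ceil = k$ceil %||% Inf),
    tabulated = {
      if (is.null(k$file)) {
        rlang::abort(sprintf("rates.%s: tabulated kernel needs `file`", field))
      }
      if (!file.exists(k$file)) {
        rlang::abort(sprintf("rates.%s: kernel table `%s` not found",
                             field, k$file))
      }
      tabulated_kernel(utils::read.csv(k$file, colClasses = c("character", "numeric")))
    },
    rlang::abort(sprintf("rates.%s: unknown kernel kind `%s`", field, k$kind))
  )
}
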