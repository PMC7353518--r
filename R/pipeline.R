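#' Ground-truth parameters of the default simulated storage study
#'
#' Three sunflower-oil batches (PV about 5, 11 and 25 mEq O2/kg oil) with
#' the rancid-odor kinetics established for crackers made from them: the
#' 20 degree C rate constants, activation energies and fresh-product
#' intensities of [cracker_fixtures()], and panel noise matching the
#' fresh-product score SDs (about 1 intensity unit for a 30-member panel).
#'
#' @param sigma_panel panel noise SD, intensity units (default 1.0).
#' @param Tref_C reference temperature for the Arrhenius parametrization.
#' @param gas_constant gas constant, J/(mol K).
#' @return list of three [kinetic_params] objects.
#' @export
default_batch_params <- function(sigma_panel = 1.0, Tref_C = 40,
                                 gas_constant = .GAS_CONSTANT_DEFAULT) {
  fx <- cracker_fixtures()
  k20 <- fx$rates$k[fx$rates$temperature_C == 20]
  lapply(seq_len(3L), function(i) {
    Ea <- fx$arrhenius$Ea_kJ_mol[i] * 1000
    # rate at Tref implied by the 20 C rate and the batch activation energy
    kref <- k20[i] * exp((Ea / gas_constant) *
                           (1 / celsius_to_kelvin(20) - 1 / celsius_to_kelvin(Tref_C)))
    kinetic_params(
      I0 = fx$fresh$rancid_intensity[i], Ea = Ea, kref = kref,
      Tref_C = Tref_C, sigma_panel = sigma_panel,
      batch_label = fx$fresh$batch_label[i], oil_pv = fx$fresh$oil_pv[i],
      gas_constant = gas_constant
    )
  })
}

#' Configuration of a full shelf-life modelling run
#'
#' @param mode `"simulate"` (generate a study with [simulate_study()]),
#'   `"csv"` (read a tidy trajectory table from `trajectories_csv`), or
#'   `"fixtures"` (use the published rate-constant table of
#'   [cracker_fixtures()] directly, skipping the zero-order stage).
#' @param trajectories_csv path to a trajectory CSV (mode `"csv"` only).
#' @param batch_params list of [kinetic_params] (mode `"simulate"`;
#'   default [default_batch_params()]).
#' @param design a [sampling_design] (mode `"simulate"`).
#' @param round_scores simulator rounding switch (mode `"simulate"`).
#' @param Tref_C Arrhenius reference temperature, degree C.
#' @param gas_constant gas constant, J/(mol K).
#' @param market_temperature_C temperature at which the rate-versus-PV
#'   model is fitted and shelf life predicted (default 20).
#' @param I0 initial intensity for shelf-life predictions; `NULL` estimates
#'   it from the data (mean fitted intercept at the market temperature) or,
#'   in fixture mode, uses the mean fresh-product score.
#' @param I_lim_set acceptability limits for the shelf-life surface.
#' @param pv_grid oil-PV grid for the surface.
#' @param days_per_month months conversion divisor.
#' @param seed RNG seed (mode `"simulate"`; overrides the design's seed).
#' @param outdir output directory for CSV/JSON artifacts; `NULL` writes
#'   nothing.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "csv", "fixtures"),
                       trajectories_csv = NULL,
                       batch_params = NULL, design = NULL,
                       round_scores = TRUE,
                       Tref_C = 40, gas_constant = .GAS_CONSTANT_DEFAULT,
                       market_temperature_C = 20,
                       I0 = NULL, I_lim_set = c(5.5, 6.0, 6.5),
                       pv_grid = seq(5, 25, by = 1),
                       days_per_month = .DAYS_PER_MONTH_DEFAULT,
                       seed = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv" && is.null(trajectories_csv)) {
    stop("mode 'csv' requires trajectories_csv", call. = FALSE)
  }
  if (mode != "csv" && !is.null(trajectories_csv)) {
    stop("trajectories_csv is only valid in mode 'csv'", call. = FALSE)
  }
  if (mode == "csv" && !file.exists(trajectories_csv)) {
    stop("trajectories_csv does not exist: ", trajectories_csv, call. = FALSE)
  }
  if (mode == "simulate") {
    if (is.null(design)) design <- sampling_design(seed = seed %||% 1L)
    if (!is.null(seed)) design$seed <- as.integer(seed)
    if (is.null(batch_params)) {
      batch_params <- default_batch_params(Tref_C = Tref_C,
                                           gas_constant = gas_constant)
    }
  }
  structure(
    list(mode = mode, trajectories_csv = trajectories_csv,
         batch_params = batch_params, design = design,
         round_scores = round_scores, Tref_C = Tref_C,
         gas_constant = gas_constant,
         market_temperature_C = market_temperature_C, I0 = I0,
         I_lim_set = I_lim_set, pv_grid = pv_grid,
         days_per_month = days_per_month, seed = seed, outdir = outdir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; nested keys `design` and
#' `batches` build the [sampling_design()] and [kinetic_params()] objects.
#' Each entry of `batches` takes `label`, `oil_pv`, `I0`, `Ea_kJ_mol`,
#' `k20` (rate at 20 degree C, intensity/day) and optional `sigma_panel`.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gas_constant <- raw$gas_constant %||% .GAS_CONSTANT_DEFAULT
  Tref_C <- raw$Tref_C %||% 40

  design <- NULL
  if (!is.null(raw$design)) {
    design <- sampling_design(
      temperatures_C = raw$design$temperatures_C %||% c(20, 40, 60),
      times_days = raw$design$times_days %||% sampling_design()$times_days,
      n_panelists = raw$design$n_panelists %||% 30,
      seed = raw$design$seed %||% raw$seed %||% 1L
    )
  }
  batch_params <- NULL
  if (!is.null(raw$batches)) {
    batch_params <- lapply(raw$batches, function(b) {
      Ea <- b$Ea_kJ_mol * 1000
      kref <- b$k20 * exp((Ea / gas_constant) *
                            (1 / celsius_to_kelvin(20) - 1 / celsius_to_kelvin(Tref_C)))
      kinetic_params(I0 = b$I0 %||% 4.33, Ea = Ea, kref = kref,
                     Tref_C = Tref_C, sigma_panel = b$sigma_panel %||% 1.0,
                     batch_label = b$label, oil_pv = b$oil_pv,
                     gas_constant = gas_constant)
    })
  }

  run_config(
    mode = raw$mode %||% "simulate",
    trajectories_csv = raw$trajectories_csv,
    batch_params = batch_params, design = design,
    round_scores = raw$round_scores %||% TRUE,
    Tref_C = Tref_C, gas_constant = gas_constant,
    market_temperature_C = raw$market_temperature_C %||% 20,
    I0 = raw$I0, I_lim_set = unlist(raw$I_lim_set) %||% c(5.5, 6.0, 6.5),
    pv_grid = unlist(raw$pv_grid) %||% seq(5, 25, by = 1),
    days_per_month = raw$days_per_month %||% .DAYS_PER_MONTH_DEFAULT,
    seed = raw$seed, outdir = raw$outdir
  )
}

#' Run the full shelf-life modelling pipeline
#'
#' Executes the chain: obtain trajectories (simulate, read, or use the
#' published rate table in fixture mode), validate, fit zero-order kinetics
#' per (batch, temperature), pool per batch through the reparametrized
#' Arrhenius model, regress the market-temperature rate on oil PV, and
#' evaluate the shelf-life surface over the configured PV grid and
#' acceptability limits. Deterministic given the seed.
#'
#' @param config a `run_config` (see [run_config()], [read_run_config()]).
#' @return a `run_report` list: `version`, `settings` (defaults actually
#'   used), `violations`, `trajectories` (tidy data frame, or NULL in
#'   fixture mode), `kinetics_table`, `arrhenius_table`, `rate_pv_model`,
#'   `I0_used`, `surface`, `warnings`. When `config$outdir` is set the
#'   tables are also written there as CSV and the report as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  trajectories <- NULL
  violations <- NULL

  if (config$mode == "fixtures") {
    kinetics_table <- cracker_fixtures()$rates
  } else {
    trajectories <- if (config$mode == "simulate") {
      trajectories_to_df(simulate_study(config$batch_params, config$design,
                                        round_scores = config$round_scores))
    } else {
      read_trajectories_csv(config$trajectories_csv)
    }
    violations <- validate_inputs(trajectories)
    if (nrow(violations) > 0L) {
      stop("stage validate_inputs: ", nrow(violations),
           " violation(s); first: row ", violations$row[1L], " ",
           violations$field[1L], " (", violations$violation[1L], ")",
           call. = FALSE)
    }
    kinetics_table <- collect(fit_kinetics_table(trajectories))
  }

  arrhenius_table <- tryCatch(
    collect(fit_arrhenius_table(kinetics_table, Tref_C = config$Tref_C,
                                gas_constant = config$gas_constant)),
    error = function(e) stop("stage fit_arrhenius: ", conditionMessage(e),
                             call. = FALSE)
  )

  market <- kinetics_table[kinetics_table$temperature_C == config$market_temperature_C, ,
                           drop = FALSE]
  if (nrow(market) < 2L) {
    stop("stage fit_rate_vs_pv: need rates for at least 2 batches at ",
         config$market_temperature_C, " C", call. = FALSE)
  }
  pv_model <- collect(fit_rate_vs_pv(market, temperature_C = config$market_temperature_C))

  I0_used <- config$I0
  if (is.null(I0_used)) {
    I0_used <- if (config$mode == "fixtures") {
      cracker_fixtures()$shelf_life$I0
    } else {
      mean(market$intercept)
    }
  }

  surface <- collect(shelf_life_surface(
    pv_model, pv_grid = config$pv_grid, ilim_set = config$I_lim_set,
    I0 = I0_used, days_per_month = config$days_per_month
  ))

  report <- list(
    version = as.character(utils::packageVersion("shelfkin")),
    settings = list(mode = config$mode, Tref_C = config$Tref_C,
                    gas_constant = config$gas_constant,
                    market_temperature_C = config$market_temperature_C,
                    days_per_month = config$days_per_month,
                    I0_used = I0_used, seed = config$seed,
                    censored_points_excluded =
                      if (!is.null(kinetics_table$n_censored_excluded))
                        sum(kinetics_table$n_censored_excluded) else 0L),
    violations = violations,
    trajectories = trajectories,
    kinetics_table = kinetics_table,
    arrhenius_table = arrhenius_table,
    rate_pv_model = pv_model,
    I0_used = I0_used,
    surface = surface,
    warnings = warnings_seen
  )
  class(report) <- "run_report"

  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> shelfkin", x$version, "- mode", x$settings$mode, "\n")
  cat("  kinetics fits:", nrow(x$kinetics_table),
      "| Arrhenius fits:", nrow(x$arrhenius_table), "\n")
  m <- x$rate_pv_model
  cat(sprintf("  k(%g C) = %.4g * PV + %.4g (r2 = %s)\n", m$temperature_C,
              m$slope, m$intercept, format(m$r2, digits = 3)))
  cat(sprintf("  I0 used = %.3f | surface rows = %d | warnings = %d\n",
              x$I0_used, nrow(x$surface), length(x$warnings)))
  invisible(x)
}

#' Write the pipeline artifacts of a run report
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$trajectories)) {
    write_trajectories_csv(report$trajectories, file.path(outdir, "trajectories.csv"))
  }
  utils::write.csv(report$kinetics_table, file.path(outdir, "kinetics_fits.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(report$arrhenius_table, file.path(outdir, "arrhenius_fits.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(report$surface, file.path(outdir, "shelf_life_surface.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  json_report <- list(
    version = report$version,
    settings = report$settings,
    rate_pv_model = unclass(report$rate_pv_model),
    arrhenius = report$arrhenius_table,
    warnings = report$warnings
  )
  jsonlite::write_json(json_report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
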