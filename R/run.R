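#' Load and validate a run configuration
#'
#' The YAML configuration drives a full reproducible run. Exactly one of
#' `inputs:` (paths to the four CSV tables) or `synthdata:` (generator
#' parameters, see [synth_config()]) must be present. Optional blocks:
#' `scenarios:` (`decline_mode`, `shock_level`, `a_max`, `tol`),
#' `preference:` (`form`, `eta`, `z0` or `target_vsl`), `discount:`
#' (`kind`, `rate`, `kappa`), `policy:` (`qaly_base`), `anchor_age`,
#' `age_range`, `output_dir`, `seed`.
#'
#' @param path YAML file path, or a pre-built list.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  has_inputs <- !is.null(cfg$inputs)
  has_synth <- !is.null(cfg$synthdata)
  if (has_inputs == has_synth) {
    abort("exactly one of `inputs:` or `synthdata:` must be configured",
          class = "qalyvsl_config_error")
  }
  if (has_inputs) {
    need <- c("life_table", "income", "consumption", "population")
    missing_keys <- setdiff(need, names(cfg$inputs))
    if (length(missing_keys) > 0) {
      abort(paste0("inputs block lacks: ", paste(missing_keys, collapse = ", ")),
            class = "qalyvsl_config_error")
    }
    absent <- !vapply(unlist(cfg$inputs[need]), file.exists, logical(1))
    if (any(absent)) {
      abort(paste0("missing input file(s): ",
                   paste(unlist(cfg$inputs[need])[absent], collapse = ", ")),
            class = "qalyvsl_config_error")
    }
  }
  structure(cfg, class = "run_config")
}

# assemble model inputs from a validated config
assemble_inputs <- function(cfg) {
  a_max <- cfg$scenarios$a_max %||% 110
  if (!is.null(cfg$synthdata)) {
    sc_args <- cfg$synthdata
    sc_args$a_max <- a_max
    if (!is.null(cfg$seed)) sc_args$seed <- cfg$seed
    scfg <- do.call(synth_config, sc_args)
    japan_like_inputs(scfg, total = cfg$population_total %||% 1.25e8)
  } else {
    ages <- 0:a_max
    table <- read_life_table(cfg$inputs$life_table,
                             dialect = cfg$inputs$dialect %||% list())
    income <- read_age_profile(cfg$inputs$income, value_col = "value",
                               ages = ages, extrapolate = "zero")
    cons <- read_age_profile(cfg$inputs$consumption, value_col = "value",
                             ages = ages, extrapolate = "last")
    popdf <- readr::read_csv(cfg$inputs$population, show_col_types = FALSE)
    list(table = table,
         profile = economic_profile(income, cons, ages = ages),
         pop = population_distribution(popdf$age, popdf$count),
         cfg = NULL)
  }
}

#' Run a full valuation from a configuration
#'
#' Builds the inputs, the equal-area scenario set and the (optionally
#' calibrated) utility family, runs [valuate()], and writes per-scenario
#' per-age CSVs (`qol`, `vsl_year`, `vsl`, `lev`, `qaly`), a summary CSV
#' (total VSL and population-weighted QALY per scenario) and a JSON
#' manifest (configuration, fingerprint, package version, timestamp) to the
#' output directory.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [read_run_config()]).
#' @param output_dir Overrides the configured output directory.
#' @return The `valuation` object, invisibly; artifacts on disk.
#' @export
run_valuation <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("no output directory configured", class = "qalyvsl_config_error")
  inp <- assemble_inputs(cfg)
  scen_cfg <- cfg$scenarios %||% list()
  scenarios <- equal_area_scenarios(
    decline_mode = scen_cfg$decline_mode %||% "multiplicative",
    shock_level = scen_cfg$shock_level %||% 0.8,
    a_max = scen_cfg$a_max %||% 110,
    tol = scen_cfg$tol %||% 1e-6)
  pref <- cfg$preference %||% list()
  disc_cfg <- cfg$discount %||% list()
  disc <- discount_spec(kind = disc_cfg$kind %||% "exponential",
                        rate = disc_cfg$rate %||% 0.01,
                        kappa = disc_cfg$kappa %||% 0.01)
  anchor <- cfg$anchor_age %||% 0
  utility <- if (!is.null(pref$z0)) {
    utility_family(form = pref$form %||% "crra", eta = pref$eta %||% 0.8,
                   z0 = pref$z0)
  } else {
    calibrate_z0(inp$table, inp$profile, scenarios[[1]], disc,
                 target_vsl = pref$target_vsl %||% 450,
                 form = pref$form %||% "crra", eta = pref$eta %||% 0.8,
                 anchor_age = anchor)
  }
  res <- valuate(inp$table, inp$profile, scenarios, utility, disc,
                 anchor_age = anchor, pop = inp$pop,
                 age_range = cfg$age_range %||% c(20, Inf))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scenarios)) {
    cur <- dplyr::filter(res$curves, .data$scenario == nm)
    readr::write_csv(cur, file.path(out_dir, paste0("curves_", nm, ".csv")))
  }
  readr::write_csv(res$vsl_years, file.path(out_dir, "vsl_years.csv"))
  readr::write_csv(res$totals, file.path(out_dir, "summary.csv"))
  manifest <- list(package_version = as.character(utils::packageVersion("qalyvsl")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   fingerprint = res$fingerprint,
                   z0 = utility$z0,
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Run the policy cost-reduction evaluation from a configuration
#'
#' Requires (or re-runs) a valuation, then evaluates [case_table()] on a
#' proportion case file and writes the resulting table.
#'
#' @param config Path to a YAML configuration or list.
#' @param case_file CSV of proportion cases (see [read_case_file()]).
#' @param valuation Optional pre-computed `valuation` (skips the re-run).
#' @param output_dir Overrides the configured output directory.
#' @return The case table, invisibly; `policy_cases.csv` on disk.
#' @export
run_policy <- function(config, case_file, valuation = NULL,
                       output_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("no output directory configured", class = "qalyvsl_config_error")
  res <- valuation %||% run_valuation(cfg, output_dir = out_dir)
  inp <- assemble_inputs(cfg)
  cases <- read_case_file(case_file)
  tab <- case_table(cases, tidy(res), inp$pop,
                    qaly_base = cfg$policy$qaly_base %||% 5,
                    age_range = cfg$age_range %||% c(0, Inf))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tab, file.path(out_dir, "policy_cases.csv"))
  invisible(tab)
}
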