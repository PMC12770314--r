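#' Mix per-scenario values by scenario proportions
#'
#' Computes \eqn{\sum_m \beta_m v_m} for proportions \eqn{\beta_m \ge 0}
#' summing to 1. Proportions supplied in percent are normalised first.
#'
#' @param values Per-scenario values (money).
#' @param proportions Scenario proportions (fractions summing to 1, or
#'   percentages summing to 100).
#' @return The mixed value; round only for presentation.
#' @export
mix_scenarios <- function(values, proportions) {
  if (length(values) != length(proportions)) {
    abort("values and proportions must have equal length",
          class = "qalyvsl_validation_error")
  }
  beta <- normalize_proportions(proportions)
  sum(beta * values)
}

normalize_proportions <- function(p) {
  if (any(p < 0)) abort("proportions must be >= 0",
                        class = "qalyvsl_validation_error")
  total <- sum(p)
  if (abs(total - 100) < 1e-6) p <- p / 100
  else if (abs(total - 1) > 1e-9) {
    abort("proportions must sum to 1 (or 100 when given in percent)",
          class = "qalyvsl_validation_error")
  }
  p
}

#' Policy cost reduction against a conventional QALY benchmark
#'
#' Evaluates
#' \deqn{\sum_a N_a (QALY_{base} - \sum_m \beta_m QALY_m(a)),}
#' the population-weighted gap between a fixed conventional value per QALY
#' and the scenario-mixed age-specific values. Positive results mean the
#' conventional benchmark is an over-estimate (a budget excess); negative
#' results a shortfall. The sum runs over ages with positive population
#' intersected with the common support of all scenarios carrying positive
#' weight (ages where any such scenario has H = 0 are excluded; the rule and
#' the ages used are recorded in the `support` attribute).
#'
#' @param qaly_curves Tibble with columns `scenario`, `age`, `qaly` (NA
#'   where undefined), e.g. `tidy(valuation)`.
#' @param pop A [population_distribution].
#' @param proportions Named or ordered per-scenario weights (fractions or
#'   percent); order must match the scenario order of `qaly_curves`.
#' @param qaly_base Conventional value per QALY (default 5 million JPY).
#' @param age_range Ages considered (default `c(0, Inf)`).
#' @return Cost reduction in trillion JPY (inputs in million JPY), with the
#'   age support as an attribute.
#' @export
cost_reduction <- function(qaly_curves, pop, proportions,
                           qaly_base = 5, age_range = c(0, Inf)) {
  stopifnot(inherits(pop, "population_distribution"))
  if (qaly_base <= 0) abort("qaly_base must be positive",
                            class = "qalyvsl_validation_error")
  scen <- unique(qaly_curves$scenario)
  beta <- normalize_proportions(proportions)
  if (length(beta) != length(scen)) {
    abort("one proportion per scenario required",
          class = "qalyvsl_validation_error")
  }
  names(beta) <- if (!is.null(names(proportions)) &&
                     all(names(proportions) %in% scen)) names(proportions) else scen
  wide <- tidyr::pivot_wider(qaly_curves[, c("scenario", "age", "qaly")],
                             names_from = "scenario", values_from = "qaly")
  active <- names(beta)[beta > 0]
  ok <- rep(TRUE, nrow(wide))
  for (nm in active) ok <- ok & !is.na(wide[[nm]])
  wide <- wide[ok & wide$age >= age_range[1] & wide$age <= age_range[2], ]
  df <- dplyr::inner_join(wide, pop, by = "age")
  df <- df[df$count > 0, ]
  if (nrow(df) == 0) abort("empty age support",
                           class = "qalyvsl_validation_error")
  mixed <- as.matrix(df[, active, drop = FALSE]) %*% beta[active]
  out <- sum(df$count * (qaly_base - mixed)) / 1e6  # million -> trillion JPY
  set_attr(out, "support", range(df$age))
}

#' Cost-reduction table over a set of proportion cases
#'
#' One [cost_reduction()] per row of `cases`; mirrors a published-style
#' comparison table of policy cost reductions under varying scenario
#' proportions.
#'
#' @param cases Data frame with a `case` id column and one proportion column
#'   per scenario (percent or fractions), e.g. columns
#'   `case, SCN1, SCN2, SCN3, SCN4`.
#' @inheritParams cost_reduction
#' @return Tibble with the case id, the proportions (as fractions) and
#'   `cost_reduction` in trillion JPY.
#' @export
case_table <- function(cases, qaly_curves, pop, qaly_base = 5,
                       age_range = c(0, Inf)) {
  scen <- unique(qaly_curves$scenario)
  missing_cols <- setdiff(scen, names(cases))
  if (length(missing_cols) > 0) {
    abort(paste0("case table lacks proportion column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "qalyvsl_format_error")
  }
  if (nrow(cases) == 0) {
    empty <- c(list(case = character(0)),
               stats::setNames(rep(list(numeric(0)), length(scen)), scen),
               list(cost_reduction = numeric(0)))
    return(tibble::as_tibble(empty))
  }
  purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    p <- as.numeric(cases[i, scen])
    tryCatch({
      beta <- normalize_proportions(p)
      cr <- cost_reduction(qaly_curves, pop, stats::setNames(beta, scen),
                           qaly_base = qaly_base, age_range = age_range)
      dplyr::bind_cols(
        tibble::tibble(case = cases$case[i]),
        tibble::as_tibble(as.list(stats::setNames(beta, scen))),
        tibble::tibble(cost_reduction = as.numeric(cr)))
    }, error = function(e) {
      abort(paste0("case ", cases$case[i], ": ", conditionMessage(e)),
            class = "qalyvsl_case_error")
    })
  })
}

#' Read a proportion case file
#'
#' CSV with columns `case, SCN1..SCN4` (proportions in percent). Percent
#' values are normalised to fractions on read.
#'
#' @param path CSV path.
#' @return Tibble of cases with fractional proportions.
#' @export
read_case_file <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"case" %in% names(df)) {
    abort("case file needs a `case` column", class = "qalyvsl_format_error")
  }
  num <- setdiff(names(df), "case")
  for (i in seq_len(nrow(df))) {
    df[i, num] <- as.list(normalize_proportions(as.numeric(df[i, num])))
  }
  df
}
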