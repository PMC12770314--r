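#' Calibrate the composite-good reference scale
#'
#' Fixes `z0` so that the total VSL of a reference scenario (by convention
#' SCN1) at the anchor age hits a target level. The VSL is strictly
#' decreasing in `z0` over the searched range (larger reference scale,
#' smaller normalised composite good, smaller Phi), so a root bracketing
#' search suffices.
#'
#' @param table A [life_table].
#' @param profile An [economic_profile].
#' @param traj Reference scenario trajectory.
#' @param disc A [discount_spec].
#' @param target_vsl Target total VSL at the anchor age, in currency units
#'   (default 450 million JPY, a representative national VSL level).
#' @param form,eta Utility family parameters (see [utility_family()]).
#' @param anchor_age Anchor age of the total VSL (default 0).
#' @param interval Search interval for `z0`.
#' @return A calibrated [utility_family].
#' @export
calibrate_z0 <- function(table, profile, traj, disc = discount_spec(),
                         target_vsl = 450, form = "crra", eta = 0.8,
                         anchor_age = 0, interval = c(1e-4, 50)) {
  f <- function(z0) {
    u <- utility_family(form = form, eta = eta, z0 = z0)
    attr(vsl_curve(table, profile, u, traj, disc, a = anchor_age), "vsl") -
      target_vsl
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi)) {
    abort(sprintf(
      "target VSL %.1f unreachable on the z0 interval [%g, %g] (VSL range [%.1f, %.1f])",
      target_vsl, interval[1], interval[2],
      target_vsl + min(lo, hi), target_vsl + max(lo, hi)),
      class = "qalyvsl_calibration_error")
  }
  z0 <- uniroot(f, interval, tol = 1e-8)$root
  utility_family(form = form, eta = eta, z0 = z0)
}

#' Run the full valuation for a set of scenarios
#'
#' For every scenario, computes the per-age VSL, LEV and QALY curves and the
#' VSL-year decomposition at the anchor age. The result carries everything
#' downstream policy evaluation needs, and has [tidy()], [glance()] and
#' [autoplot()] methods.
#'
#' @param table A [life_table].
#' @param profile An [economic_profile] on ages `0..a_max`.
#' @param scenarios Named list of `qol_trajectory` objects (e.g. from
#'   [equal_area_scenarios()]).
#' @param utility A [utility_family].
#' @param disc A [discount_spec].
#' @param ages Ages at which VSL/LEV/QALY are evaluated (default: every
#'   grid age).
#' @param anchor_age Age anchoring the total VSL and the VSL-year curve.
#' @param pop Optional [population_distribution] for weighted summaries.
#' @param age_range Age range of the population weighting.
#' @return An object of class `valuation`.
#' @export
valuate <- function(table, profile, scenarios, utility,
                    disc = discount_spec(), ages = NULL, anchor_age = 0,
                    pop = NULL, age_range = c(20, Inf)) {
  stopifnot(is.list(scenarios), length(scenarios) > 0,
            !is.null(names(scenarios)))
  ages <- ages %||% profile$age
  curves <- purrr::imap_dfr(scenarios, function(traj, nm) {
    lev <- vapply(ages, function(a)
      lev_value(table, profile, utility, traj, disc, a = a), numeric(1))
    vsl <- vapply(ages, function(a)
      attr(vsl_curve(table, profile, utility, traj, disc, a = a), "vsl"),
      numeric(1))
    h <- traj$qol[match(ages, traj$age)]
    tibble::tibble(scenario = nm, age = ages, qol = h, vsl = vsl, lev = lev,
                   qaly = ifelse(h > 0, lev / h, NA_real_))
  })
  vsl_years <- purrr::imap_dfr(scenarios, function(traj, nm) {
    vc <- vsl_curve(table, profile, utility, traj, disc, a = anchor_age)
    tibble::tibble(scenario = nm, age = vc$age, vsl_year = vc$vsl_year)
  })
  totals <- dplyr::summarise(
    dplyr::group_by(vsl_years, .data$scenario),
    total_vsl = sum(.data$vsl_year), .groups = "drop")
  if (!is.null(pop)) {
    wq <- purrr::imap_dbl(scenarios, function(traj, nm) {
      q <- dplyr::filter(curves, .data$scenario == nm)[, c("age", "qaly")]
      population_weighted_qaly(q, pop, age_range = age_range)
    })
    totals$weighted_qaly <- wq[totals$scenario]
  }
  structure(
    list(curves = curves, vsl_years = vsl_years, totals = totals,
         scenarios = scenarios, utility = utility, disc = disc,
         anchor_age = anchor_age, pop = pop, age_range = age_range,
         fingerprint = config_fingerprint(list(
           utility = unclass(utility), disc = unclass(disc),
           anchor_age = anchor_age,
           terminal_ages = lapply(scenarios, attr, "terminal_age")))),
    class = "valuation")
}

config_fingerprint <- function(x) {
  # stable short hash of the run configuration (no external digest dependency)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' @export
print.valuation <- function(x, ...) {
  cat("<valuation> ", nrow(x$totals), " scenario(s), anchor age ",
      x$anchor_age, ", fingerprint ", x$fingerprint, "\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' @rdname valuate
#' @param x A `valuation` object.
#' @param ... Unused.
#' @export
tidy.valuation <- function(x, ...) x$curves

#' @rdname valuate
#' @export
glance.valuation <- function(x, ...) x$totals

#' Plot a valuation result
#'
#' @param object A `valuation` object.
#' @param what `"vsl_year"`, `"qaly"`, `"vsl"`, `"lev"` or `"qol"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.valuation <- function(object, what = c("vsl_year", "qaly", "vsl",
                                                "lev", "qol"), ...) {
  what <- match.arg(what)
  if (what == "vsl_year") {
    df <- object$vsl_years
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$vsl_year,
                                          colour = .data$scenario,
                                          linetype = .data$scenario)) +
      ggplot2::labs(y = "VSL-year (million JPY)")
  } else {
    df <- object$curves
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$age, .data[[what]],
                                          colour = .data$scenario,
                                          linetype = .data$scenario)) +
      ggplot2::labs(y = what)
  }
  p + ggplot2::geom_line() + ggplot2::labs(x = "age (years)") +
    ggplot2::theme_minimal()
}

#' Sensitivity sweep over one model parameter
#'
#' Re-runs the full valuation for each value of a named parameter and
#' returns a tidy table of totals. Supported parameters: `"r"` (interest
#' rate), `"kappa"` (with hyperbolic discounting), `"eta"`, `"utility"`
#' (family form), `"a_max"`, `"shock_level"` (SCN4 drop).
#'
#' @param table,profile,pop Base inputs ([life_table], [economic_profile],
#'   [population_distribution]).
#' @param parameter Parameter name.
#' @param values Values to sweep.
#' @param utility Base [utility_family] (its `z0` is kept fixed across the
#'   sweep so runs are comparable).
#' @param disc Base [discount_spec].
#' @param decline_mode,shock_level,a_max Scenario construction settings.
#' @param anchor_age,age_range Passed to [valuate()].
#' @return Tibble with one row per (value, scenario): `parameter`, `value`,
#'   `scenario`, `total_vsl`, `weighted_qaly` (if `pop` given).
#' @export
sensitivity_sweep <- function(table, profile, pop = NULL,
                              parameter, values,
                              utility = utility_family(),
                              disc = discount_spec(),
                              decline_mode = "multiplicative",
                              shock_level = 0.8, a_max = 110,
                              anchor_age = 0, age_range = c(20, Inf)) {
  allowed <- c("r", "kappa", "eta", "utility", "a_max", "shock_level")
  if (!parameter %in% allowed) {
    abort(paste0("unknown sweep parameter: ", parameter,
                 " (supported: ", paste(allowed, collapse = ", "), ")"),
          class = "qalyvsl_validation_error")
  }
  purrr::map_dfr(values, function(v) {
    u <- utility; d <- disc; sl <- shock_level; am <- a_max
    if (parameter == "r") d <- discount_spec("exponential", rate = as.numeric(v))
    if (parameter == "kappa") d <- discount_spec("hyperbolic", kappa = as.numeric(v))
    if (parameter == "eta") u <- utility_family("crra", eta = as.numeric(v), z0 = utility$z0)
    if (parameter == "utility") {
      u <- if (v == "log") utility_family("log", z0 = utility$z0)
      else utility_family("crra", eta = utility$eta %||% 0.8, z0 = utility$z0)
    }
    if (parameter == "a_max") am <- as.numeric(v)
    if (parameter == "shock_level") sl <- as.numeric(v)
    scen <- equal_area_scenarios(decline_mode, shock_level = sl, a_max = am)
    keep <- profile$age <= am
    prof <- economic_profile(income = profile$full_income[keep],
                             consumption = profile$full_consumption[keep],
                             ages = profile$age[keep],
                             currency_unit = attr(profile, "currency_unit") %||% "million JPY")
    res <- valuate(table, prof, scen, u, d, anchor_age = anchor_age,
                   pop = pop, age_range = age_range)
    dplyr::mutate(glance(res), parameter = parameter, value = v,
                  .before = 1)
  })
}
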