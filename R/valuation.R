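#' Discounting specification
#'
#' Exponential discounting \eqn{e^{-r(t-a)}} at interest rate `rate`
#' (default 1% per year), or hyperbolic discounting
#' \eqn{1/(1 + \kappa(t-a))} with `kappa` (default 0.01 per year).
#'
#' @param kind `"exponential"` or `"hyperbolic"`.
#' @param rate Interest rate per year (exponential).
#' @param kappa Hyperbolic parameter per year.
#' @return A `discount_spec` list.
#' @export
discount_spec <- function(kind = c("exponential", "hyperbolic"),
                          rate = 0.01, kappa = 0.01) {
  kind <- match.arg(kind)
  if (rate < 0 || kappa < 0) {
    abort("discount parameters must be >= 0", class = "qalyvsl_validation_error")
  }
  structure(list(kind = kind, rate = rate, kappa = kappa),
            class = "discount_spec")
}

#' Discount factor between two ages
#'
#' @param t Future age(s), each `>= a`.
#' @param a Present age (scalar).
#' @param spec A [discount_spec].
#' @return Dimensionless factor(s) in (0, 1].
#' @export
discount_factor <- function(t, a, spec = discount_spec()) {
  stopifnot(inherits(spec, "discount_spec"))
  if (any(t < a)) abort("t must be >= a", class = "qalyvsl_domain_error")
  dt <- t - a
  if (spec$kind == "exponential") exp(-spec$rate * dt) else 1 / (1 + spec$kappa * dt)
}

# per-age monetary flow of the valuation integrand: y^F + Phi(z) c^F
flow_series <- function(profile, traj, utility) {
  z <- composite_good(profile, traj)$z
  profile$full_income + phi(z, utility) * profile$full_consumption
}

#' VSL-year curve and total VSL at an age
#'
#' The value of a statistical life at age `a` is the discounted expected
#' flow of full income plus Phi-weighted full consumption over the remaining
#' lifetime:
#' \deqn{VSL_m(a) = \int_a^\infty e^{-r(t-a)} (y^F(t) + \Phi_m(z(t)) c^F(t))
#'   S(t,a)\, dt,}
#' evaluated by the composite trapezoid rule on the unit age grid (the
#' resolution of the inputs), truncated where survival vanishes. The
#' VSL-year at age t is the trapezoid-weighted integrand contribution, so
#' the VSL-years sum exactly to the total VSL.
#'
#' @param table A [life_table].
#' @param profile An [economic_profile] on ages `0..a_max`.
#' @param utility A [utility_family].
#' @param traj A `qol_trajectory` on the same grid.
#' @param disc A [discount_spec].
#' @param a Anchor age (default 0).
#' @param refine Integer grid-refinement factor (default 1: annual steps);
#'   inputs are linearly interpolated onto the finer grid.
#' @return Tibble with columns `age`, `integrand`, `vsl_year`; attribute
#'   `vsl` holds the total. `sum(out$vsl_year)` equals `attr(out, "vsl")`.
#' @export
vsl_curve <- function(table, profile, utility, traj, disc = discount_spec(),
                      a = 0, refine = 1) {
  check_common_grid(profile, traj)
  a_max <- max(profile$age)
  if (a < 0 || a > a_max) abort("a outside the age grid",
                                class = "qalyvsl_domain_error")
  step <- 1 / refine
  t <- seq(a, a_max, by = step)
  flow <- flow_at(t, profile, traj, utility)
  g <- discount_factor(t, a, disc) * flow * survival_prob(table, t, a)
  w <- trapz_weights(length(t), step)
  out <- tibble::tibble(age = t, integrand = g, vsl_year = w * g)
  set_attr(set_attr(out, "vsl", sum(w * g)), "anchor_age", a)
}

# integrand flow evaluated at arbitrary (possibly refined) ages
flow_at <- function(t, profile, traj, utility) {
  if (all(t %in% profile$age)) {
    f <- flow_series(profile, traj, utility)
    return(f[match(t, profile$age)])
  }
  y <- approx(profile$age, profile$full_income, xout = t)$y
  cf <- approx(profile$age, profile$full_consumption, xout = t)$y
  h <- approx(traj$age, traj$qol, xout = t)$y
  y + phi(h * cf, utility) * cf
}

trapz_weights <- function(n, step) {
  if (n == 1) return(0)
  w <- rep(step, n)
  w[c(1, n)] <- step / 2
  w
}

check_common_grid <- function(profile, traj) {
  if (!identical(as.numeric(profile$age), as.numeric(traj$age))) {
    abort("inputs must share a common age grid",
          class = "qalyvsl_validation_error")
  }
}

#' Life-extension value at an age
#'
#' The LEV prices a one-year outward shift of the survival curve: the same
#' discounted flow as [vsl_curve()], weighted by the unit-area survival
#' increment \eqn{S(t-1, a) - S(t, a)} instead of \eqn{S(t, a)}:
#' \deqn{LEV_m(a) = \int_a^\infty e^{-r(t-a)} (y^F(t) + \Phi_m(z(t)) c^F(t))
#'   (S(t-1,a) - S(t,a))\, dt.}
#' For `t` within one year of `a`, `S(t-1, a)` is 1 (the person cannot have
#' died before `a`). The integral runs to one year past the age grid so the
#' final survival increment is fully captured; the flow there is carried
#' from the last grid age.
#'
#' @inheritParams vsl_curve
#' @return The LEV at age `a`, in the profile's currency units.
#' @export
lev_value <- function(table, profile, utility, traj, disc = discount_spec(),
                      a = 0, refine = 1) {
  check_common_grid(profile, traj)
  a_max <- max(profile$age)
  if (a < 0 || a > a_max) abort("a outside the age grid",
                                class = "qalyvsl_domain_error")
  step <- 1 / refine
  t <- seq(a, a_max + 1, by = step)
  flow <- flow_at(pmin(t, a_max), profile, traj, utility)
  s_now <- survival_prob(table, t, a)
  s_lag <- ifelse(t - 1 < a, 1, survival_prob(table, pmax(t - 1, a), a))
  g <- discount_factor(t, a, disc) * flow * (s_lag - s_now)
  sum(trapz_weights(length(t), step) * g)
}

#' Monetary value of a QALY at an age
#'
#' Normalises the life-extension value by current QoL:
#' \eqn{QALY_m(a) = LEV_m(a) / H_m(a)} — the value of extending a year
#' lived in full health. Undefined at ages past the scenario's terminal age
#' (H = 0), which is reported as an error rather than silently skipped.
#'
#' @param lev_value LEV at age `a` (money).
#' @param traj The scenario's `qol_trajectory`.
#' @param a Age.
#' @return Money per QALY.
#' @export
qaly_value <- function(lev_value, traj, a) {
  h <- traj$qol[match(a, traj$age)]
  if (is.na(h)) abort("age not on the trajectory grid",
                      class = "qalyvsl_domain_error")
  if (h <= 0) {
    abort(sprintf("QALY undefined at age %s: beyond the scenario's terminal age (H = 0)", a),
          class = "qalyvsl_undefined_age_error")
  }
  lev_value / h
}

#' Population-weighted average of a per-age QALY curve
#'
#' \eqn{\sum_a N_a\, QALY(a) / \sum_a N_a} over the configured age range,
#' restricted to ages where the curve is defined (H > 0).
#'
#' @param qaly Tibble with columns `age`, `qaly` (NA where undefined).
#' @param pop A [population_distribution].
#' @param age_range Length-2 numeric, default `c(20, Inf)`: adult ages.
#' @return Weighted mean, in the curve's currency units.
#' @export
population_weighted_qaly <- function(qaly, pop, age_range = c(20, Inf)) {
  stopifnot(inherits(pop, "population_distribution"))
  df <- dplyr::inner_join(qaly, pop, by = "age")
  df <- dplyr::filter(df, .data$age >= age_range[1],
                      .data$age <= age_range[2], !is.na(.data$qaly))
  if (nrow(df) == 0 || sum(df$count) <= 0) {
    abort("no overlap between the QALY curve and the population",
          class = "qalyvsl_validation_error")
  }
  sum(df$count * df$qaly) / sum(df$count)
}
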