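#' Utility family for the composite consumption–leisure good
#'
#' The valuation integrand weights full consumption by the elasticity term
#' \eqn{\Phi(z) = u(z) / (z\,u'(z)) - 1}, where z is the composite good in
#' units of the reference scale `z0`. Two families are supported:
#' * `"crra"`: \eqn{u(s) = (s^{1-\eta} - 1)/(1-\eta)}, giving
#'   \eqn{\Phi = (1 - s^{\eta-1})/(1-\eta) - 1};
#' * `"log"`: \eqn{u(s) = \ln s}, the \eqn{\eta \to 1} limit, giving
#'   \eqn{\Phi = \ln s - 1};
#' with \eqn{s = z / z_0}.
#'
#' @param form `"crra"` or `"log"`.
#' @param eta Relative risk aversion (CRRA only; `eta >= 0`, `eta != 1`).
#' @param z0 Reference scale of the composite good, in the same currency
#'   units as consumption (must be positive). Usually set by
#'   [calibrate_z0()].
#' @return A `utility_family` list.
#' @export
utility_family <- function(form = c("crra", "log"), eta = 0.8, z0 = 1) {
  form <- match.arg(form)
  if (form == "crra" && (eta < 0 || eta == 1)) {
    abort("crra requires eta >= 0 and eta != 1 (use form = 'log' for eta = 1)",
          class = "qalyvsl_validation_error")
  }
  if (z0 <= 0) abort("z0 must be positive", class = "qalyvsl_validation_error")
  structure(list(form = form, eta = if (form == "crra") eta, z0 = z0),
            class = "utility_family")
}

#' Elasticity weight on full consumption
#'
#' Computes \eqn{\Phi(z)} for the given utility family, floored at -1 so the
#' consumption term of the valuation integrand never falls below
#' \eqn{-c^F}: at z = 0 (death or zero QoL) the weight is exactly -1, and
#' the floor keeps the integrand bounded and continuous in the H -> 0 limit.
#'
#' @param z Composite-good values (non-negative).
#' @param utility A [utility_family].
#' @param floor Lower bound on the weight (default -1).
#' @return Numeric vector of dimensionless weights.
#' @export
phi <- function(z, utility, floor = -1) {
  stopifnot(inherits(utility, "utility_family"))
  if (any(z < 0)) abort("z must be non-negative", class = "qalyvsl_domain_error")
  s <- z / utility$z0
  out <- rep(floor, length(s))
  pos <- s > 0
  if (utility$form == "log") {
    out[pos] <- log(s[pos]) - 1
  } else {
    eta <- utility$eta
    out[pos] <- (1 - s[pos]^(eta - 1)) / (1 - eta) - 1
  }
  pmax(out, floor)
}

#' Composite good under a QoL trajectory
#'
#' The composite good z(t) bundles consumption and leisure; full consumption
#' already carries both, so a QoL trajectory scales its enjoyability:
#' \eqn{z_m(t) = H_m(t)\, c^F(t)} (multiplicative coupling, the default).
#' A custom `coupling` function `(qol, consumption) -> z` may be supplied.
#'
#' @param profile An [economic_profile].
#' @param traj A [build_trajectory()] result on the same age grid.
#' @param coupling Function of `(qol, consumption)`; default multiplies.
#' @return Tibble with columns `age`, `z`.
#' @export
composite_good <- function(profile, traj, coupling = `*`) {
  stopifnot(inherits(profile, "economic_profile"),
            inherits(traj, "qol_trajectory"))
  if (!identical(as.numeric(profile$age), as.numeric(traj$age))) {
    abort("profile and trajectory must share the same age grid",
          class = "qalyvsl_validation_error")
  }
  tibble::tibble(age = profile$age,
                 z = coupling(traj$qol, profile$full_consumption))
}
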