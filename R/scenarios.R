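#' Declare a lifetime quality-of-life scenario
#'
#' A scenario describes how health-related quality of life H(a) evolves with
#' age: unity through childhood and early adulthood, then piecewise annual
#' decline. Declines may be `"multiplicative"` (H shrinks by a proportion
#' each year, the default) or `"linear"` (a fixed absolute step). Plateaus
#' suspend the decline over an age range; an optional shock drops H to a
#' given level at a given age. A real-valued `terminal_age` truncates the
#' trajectory to 0 beyond it — usually left `NA` and solved by
#' [solve_terminal_age()] under the equal-area constraint.
#'
#' @param name Scenario label.
#' @param segments Tibble or data frame with columns `start_age`,
#'   `rate` (annual decline, proportion or absolute step depending on mode),
#'   strictly increasing in `start_age`.
#' @param plateaus Optional tibble with columns `start`, `end`: no decline is
#'   applied to year steps starting within `[start, end)`.
#' @param shock Optional `c(age, level)`: H is set to `level` at `age`.
#' @param decline_mode `"multiplicative"` or `"linear"`.
#' @param terminal_age Age at which H reaches 0 (real-valued), or `NA`.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, segments,
                          plateaus = NULL, shock = NULL,
                          decline_mode = c("multiplicative", "linear"),
                          terminal_age = NA_real_) {
  decline_mode <- match.arg(decline_mode)
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("start_age", "rate") %in% names(segments)))
  if (nrow(segments) > 1 && any(diff(segments$start_age) <= 0)) {
    abort("segment start ages must be strictly increasing",
          class = "qalyvsl_validation_error")
  }
  if (any(segments$rate < 0)) {
    abort("decline rates must be >= 0", class = "qalyvsl_validation_error")
  }
  if (!is.null(shock)) {
    if (length(shock) != 2 || shock[2] <= 0 || shock[2] > 1) {
      abort("shock must be c(age, level) with level in (0, 1]",
            class = "qalyvsl_validation_error")
    }
  }
  structure(
    list(name = name, segments = segments,
         plateaus = if (!is.null(plateaus)) tibble::as_tibble(plateaus),
         shock = shock, decline_mode = decline_mode,
         terminal_age = terminal_age),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, " (", x$decline_mode, ")",
      if (!is.na(x$terminal_age)) paste0(", terminal age ",
                                         signif(x$terminal_age, 6)),
      "\n", sep = "")
  invisible(x)
}

#' Built-in QoL scenario presets
#'
#' Four stylised lifetime health trajectories:
#' * `SCN1` — general ageing: QoL falls 2% per year after age 50.
#' * `SCN2` — healthy ageing: QoL falls 1% per year after age 50.
#' * `SCN3` — early chronic decline: 1% per year from age 30, stable between
#'   50 and 70, then 1% per year again.
#' * `SCN4` — sudden event: a sharp drop at age 60 (to `shock_level`), then
#'   1% per year.
#'
#' @param name One of `"SCN1"`–`"SCN4"`.
#' @param decline_mode `"multiplicative"` (default) or `"linear"`.
#' @param shock_level Post-shock QoL level for SCN4 (default 0.8; the drop
#'   magnitude is a modelling choice, see the package vignette).
#' @return A [scenario_spec].
#' @export
scn_preset <- function(name, decline_mode = c("multiplicative", "linear"),
                       shock_level = 0.8) {
  decline_mode <- match.arg(decline_mode)
  seg <- function(...) tibble::tibble(...)
  switch(
    name,
    SCN1 = scenario_spec("SCN1", seg(start_age = 50, rate = 0.02),
                         decline_mode = decline_mode),
    SCN2 = scenario_spec("SCN2", seg(start_age = 50, rate = 0.01),
                         decline_mode = decline_mode),
    SCN3 = scenario_spec("SCN3", seg(start_age = 30, rate = 0.01),
                         plateaus = seg(start = 50, end = 70),
                         decline_mode = decline_mode),
    SCN4 = scenario_spec("SCN4", seg(start_age = 60, rate = 0.01),
                         shock = c(60, shock_level),
                         decline_mode = decline_mode),
    abort(paste0("unknown preset: ", name), class = "qalyvsl_validation_error")
  )
}

# untruncated H on the unit grid 0..a_max, before any terminal-age cut
untruncated_qol <- function(spec, a_max) {
  ages <- 0:a_max
  h <- rep(1, length(ages))
  rate_at <- function(a) {
    # decline rate applying to the year step a -> a + 1
    active <- spec$segments$rate[spec$segments$start_age <= a]
    r <- if (length(active) > 0) active[length(active)] else 0
    if (!is.null(spec$plateaus) &&
        any(a >= spec$plateaus$start & a < spec$plateaus$end)) {
      r <- 0
    }
    r
  }
  for (i in seq_len(a_max)) {
    a <- ages[i]
    h[i + 1] <- if (spec$decline_mode == "multiplicative") {
      h[i] * (1 - rate_at(a))
    } else {
      h[i] - rate_at(a)
    }
    if (!is.null(spec$shock) && ages[i + 1] == spec$shock[1]) {
      if (spec$shock[2] > h[i + 1] + 1e-12) {
        abort("shock level exceeds the trajectory value at the shock age",
              class = "qalyvsl_validation_error")
      }
      h[i + 1] <- spec$shock[2]
    }
  }
  pmax(h, 0)
}

# area of the trajectory truncated at real-valued age tau, with the partial
# final year integrated under linear interpolation of H
area_at_truncation <- function(h, tau, from = 0) {
  ages <- seq_along(h) - 1
  a_max <- ages[length(ages)]
  tau <- min(tau, a_max)
  k <- floor(tau)
  frac <- tau - k
  idx <- ages >= from & ages <= k
  base <- if (sum(idx) >= 2) trapz_unit(h[idx]) else 0
  partial <- 0
  if (frac > 0 && k < a_max) {
    h0 <- h[k + 1]
    h1 <- h[k + 2]
    partial <- frac * h0 + frac^2 / 2 * (h1 - h0)
  }
  base + partial
}

# composite trapezoid with unit spacing
trapz_unit <- function(y) sum((y[-1] + y[-length(y)]) / 2)

#' Build the QoL trajectory for a scenario
#'
#' Evaluates H(a) on the unit age grid `0..a_max`: H = 1 before the first
#' decline age, then the scenario's piecewise decline, plateaus and shock,
#' clipped at 0. If the spec carries a (possibly real-valued) `terminal_age`,
#' H is set to 0 at all grid ages beyond it.
#'
#' @param spec A [scenario_spec].
#' @param a_max Upper age of the grid (default 110).
#' @return Tibble of class `qol_trajectory` with columns `age`, `qol`;
#'   attributes `spec`, `terminal_age`, and the untruncated curve.
#' @export
build_trajectory <- function(spec, a_max = 110) {
  stopifnot(inherits(spec, "scenario_spec"))
  h_raw <- untruncated_qol(spec, a_max)
  ages <- 0:a_max
  tau <- spec$terminal_age
  if (is.na(tau)) {
    # natural terminal age: first grid age with H == 0, else open at a_max
    hit <- which(h_raw <= 0)
    tau <- if (length(hit) > 0) ages[hit[1]] else a_max
  }
  h <- h_raw
  h[ages > tau] <- 0
  out <- tibble::tibble(age = as.numeric(ages), qol = h)
  structure(out, class = c("qol_trajectory", class(tibble::tibble()))) |>
    set_attr("spec", spec) |>
    set_attr("terminal_age", tau) |>
    set_attr("untruncated", h_raw)
}

#' Area under a QoL trajectory, in QoL-years
#'
#' Trapezoidal integral of H over `[from, a_max]`, honouring a real-valued
#' terminal age: the final partial year contributes proportionally.
#'
#' @param traj A [build_trajectory()] result.
#' @param from Lower bound of the area accounting (default 0).
#' @return Area in QoL-years.
#' @export
trajectory_area <- function(traj, from = 0) {
  stopifnot(inherits(traj, "qol_trajectory"))
  area_at_truncation(attr(traj, "untruncated"),
                     attr(traj, "terminal_age"), from = from)
}

#' Solve the terminal age that matches a target QoL area
#'
#' The equal-area constraint fixes every scenario's lifetime QoL area to a
#' reference (by construction SCN1's), by truncating the trajectory — moving
#' the age at which QoL reaches 0 — rather than reshaping the decline. The
#' area is continuous and strictly increasing in the truncation age, so
#' bisection converges unconditionally.
#'
#' @param spec A [scenario_spec] (its `terminal_age` is ignored).
#' @param target_area Target area in QoL-years.
#' @param a_max Grid upper age.
#' @param tol Absolute tolerance on the area (default 1e-6 QoL-years).
#' @param from Lower bound of the area accounting (default 0).
#' @return The spec with `terminal_age` set so that
#'   `trajectory_area(build_trajectory(spec, a_max), from)` equals
#'   `target_area` within `tol`.
#' @export
solve_terminal_age <- function(spec, target_area, a_max = 110,
                               tol = 1e-6, from = 0) {
  stopifnot(inherits(spec, "scenario_spec"))
  h <- untruncated_qol(spec, a_max)
  full <- area_at_truncation(h, a_max, from = from)
  if (full < target_area - tol) {
    abort(sprintf(
      "equal-area constraint infeasible for %s: untruncated area %.6f < target %.6f",
      spec$name, full, target_area), class = "qalyvsl_infeasible_error")
  }
  lo <- min(spec$segments$start_age)
  if (!is.null(spec$shock)) lo <- min(lo, spec$shock[1])
  hi <- a_max
  if (area_at_truncation(h, lo, from = from) > target_area) {
    abort("target area below the pre-decline area; cannot truncate that early",
          class = "qalyvsl_infeasible_error")
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (area_at_truncation(h, mid, from = from) < target_area) lo <- mid
    else hi <- mid
    if (abs(area_at_truncation(h, (lo + hi) / 2, from = from) -
            target_area) <= tol && (hi - lo) < 0.5) break
  }
  spec$terminal_age <- (lo + hi) / 2
  spec
}

#' Build the four preset scenarios under the equal-area constraint
#'
#' SCN1 defines the reference area; SCN2–SCN4 get their terminal ages solved
#' so all four trajectories enclose the same number of QoL-years.
#'
#' @inheritParams scn_preset
#' @param a_max Grid upper age.
#' @param tol Area tolerance passed to [solve_terminal_age()].
#' @param from Lower bound of the area accounting.
#' @return Named list of four `qol_trajectory` objects.
#' @export
equal_area_scenarios <- function(decline_mode = c("multiplicative", "linear"),
                                 shock_level = 0.8, a_max = 110,
                                 tol = 1e-6, from = 0) {
  decline_mode <- match.arg(decline_mode)
  scn1 <- build_trajectory(scn_preset("SCN1", decline_mode), a_max)
  target <- trajectory_area(scn1, from = from)
  others <- lapply(c("SCN2", "SCN3", "SCN4"), function(nm) {
    spec <- scn_preset(nm, decline_mode, shock_level = shock_level)
    build_trajectory(solve_terminal_age(spec, target, a_max = a_max,
                                        tol = tol, from = from), a_max)
  })
  stats::setNames(c(list(scn1), others), c("SCN1", "SCN2", "SCN3", "SCN4"))
}
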