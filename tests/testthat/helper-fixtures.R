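# shared fixtures, built in code

# tiny triangular survival instance used by the hand-sum oracles
toy_table <- function(lx = c(1, 0.5, 0.25)) {
  life_table(age = seq_along(lx) - 1, lx = lx)
}

# constant-flow profile: income v, zero consumption, so the integrand flow
# is exactly v regardless of the utility family
const_flow_profile <- function(v, a_max) {
  economic_profile(income = rep(v, a_max + 1),
                   consumption = rep(0, a_max + 1), ages = 0:a_max)
}

full_health <- function(a_max) {
  build_trajectory(scenario_spec("full", tibble::tibble(start_age = a_max,
                                                        rate = 0)),
                   a_max = a_max)
}

any_utility <- function() utility_family("crra", eta = 0.8, z0 = 1)

# explicit discrete trapezoid sum, independent of the package quadrature
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# the shipped japan-like preset run, computed once and cached across files
preset_cache <- new.env(parent = emptyenv())

preset_run <- function() {
  if (is.null(preset_cache$res)) {
    inp <- japan_like_inputs()
    scen <- equal_area_scenarios()
    u <- calibrate_z0(inp$table, inp$profile, scen$SCN1)
    preset_cache$inp <- inp
    preset_cache$scen <- scen
    preset_cache$utility <- u
    preset_cache$res <- valuate(inp$table, inp$profile, scen, u,
                                pop = inp$pop)
  }
  preset_cache
}

table2_cases <- function() {
  data.frame(case = 1:5,
             SCN1 = c(100, 70, 50, 30, 10),
             SCN2 = c(0, 0, 20, 40, 60),
             SCN3 = c(0, 15, 15, 15, 15),
             SCN4 = c(0, 15, 15, 15, 15))
}
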