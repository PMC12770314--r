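#' Configuration for the synthetic socioeconomic data generator
#'
#' The generator emulates the statistical shape of the aggregate Japanese
#' inputs the valuation consumes: a Gompertz–Makeham survival curve closing
#' near age 110, a hump-shaped full-income profile peaking mid-career and
#' tapering to zero after retirement, a flatter always-positive full
#' consumption profile, and an aged two-bump population pyramid. Curves are
#' deterministic closed forms; optional multiplicative noise (seeded)
#' exercises reader robustness only.
#'
#' @param seed Integer seed for the optional noise draws.
#' @param a_max Upper age of the grid (default 110).
#' @param makeham Age-independent hazard floor (per year).
#' @param gompertz_level,gompertz_slope Gompertz parameters B and C of the
#'   hazard \eqn{\mu(x) = A + B e^{C x}}.
#' @param wage_peak_age,wage_peak_level,wage_spread Full-income hump:
#'   location (years), height (million JPY/year) and width (years).
#' @param retirement_age Age by which full income has tapered to 0.
#' @param cons_base,cons_slope,cons_rise_start,cons_cap_age,cons_old_taper
#'   Full consumption: young-age base level (million JPY/year), annual rise
#'   from `cons_rise_start` up to `cons_cap_age` (full consumption bundles
#'   market consumption with the value of non-market time, which grows into
#'   retirement), then flat, scaled down linearly to a fraction
#'   `cons_old_taper` of the cap by the top age (1 = no old-age taper).
#' @param pyramid_modes,pyramid_weights,pyramid_spreads Population pyramid
#'   mixture components (modal ages, weights, widths).
#' @param noise_sd Standard deviation of multiplicative log-normal noise on
#'   the profiles (default 0 = off).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, a_max = 110,
                         makeham = 2e-4,
                         gompertz_level = 4.6e-6, gompertz_slope = 0.115,
                         wage_peak_age = 50, wage_peak_level = 8,
                         wage_spread = 16, retirement_age = 75,
                         cons_base = 4.0, cons_slope = 0.06,
                         cons_rise_start = 25, cons_cap_age = 75,
                         cons_old_taper = 0.6,
                         pyramid_modes = c(48, 73), pyramid_weights = c(0.55, 0.45),
                         pyramid_spreads = c(16, 9),
                         noise_sd = 0) {
  cfg <- list(seed = as.integer(seed), a_max = a_max, makeham = makeham,
              gompertz_level = gompertz_level, gompertz_slope = gompertz_slope,
              wage_peak_age = wage_peak_age, wage_peak_level = wage_peak_level,
              wage_spread = wage_spread, retirement_age = retirement_age,
              cons_base = cons_base, cons_slope = cons_slope,
              cons_rise_start = cons_rise_start, cons_cap_age = cons_cap_age,
              cons_old_taper = cons_old_taper,
              pyramid_modes = pyramid_modes, pyramid_weights = pyramid_weights,
              pyramid_spreads = pyramid_spreads, noise_sd = noise_sd)
  rates <- c(cfg$makeham, cfg$gompertz_slope, cfg$wage_peak_level,
             cfg$cons_base)
  if (any(rates <= 0) || cfg$gompertz_level < 0) {
    abort("rates and levels must be positive (gompertz_level may be 0)",
          class = "qalyvsl_validation_error")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a Gompertz–Makeham life table
#'
#' Hazard \eqn{\mu(x) = A + B e^{C x}}; survivorship
#' \eqn{l(x) = \exp(-A x - (B/C)(e^{C x} - 1))}. Deterministic given the
#' parameters. Warns if the table does not close (l at the top age above
#' 1e-3).
#'
#' @param cfg A [synth_config].
#' @return A [life_table].
#' @export
generate_life_table <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  x <- 0:cfg$a_max
  A <- cfg$makeham; B <- cfg$gompertz_level; C <- cfg$gompertz_slope
  lx <- exp(-A * x - (B / C) * (exp(C * x) - 1))
  if (lx[length(lx)] > 1e-3) {
    warn(sprintf("life table tail not closed: l(%d) = %.2g",
                 cfg$a_max, lx[length(lx)]))
  }
  life_table(age = x, lx = lx)
}

#' Generate full-income and full-consumption profiles
#'
#' Full income is a Gaussian hump peaking mid-career, multiplied by a
#' smooth taper that reaches 0 at `retirement_age` (and exactly 0 beyond),
#' and 0 before age 18. Full consumption rises from its young-age base into
#' retirement (the value of non-market time grows as market work winds
#' down), then declines gently in deep old age; it is positive at every
#' age. With `noise_sd > 0`, seeded multiplicative log-normal noise is
#' applied to both.
#'
#' @param cfg A [synth_config].
#' @return An [economic_profile] in million JPY.
#' @export
generate_profiles <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  x <- 0:cfg$a_max
  hump <- exp(-((x - cfg$wage_peak_age)^2) / (2 * cfg$wage_spread^2))
  taper <- pmin(1, pmax(0, (cfg$retirement_age - x) /
                             (cfg$retirement_age - cfg$wage_peak_age)))
  entry <- pmin(1, pmax(0, (x - 18) / 7))
  income <- cfg$wage_peak_level * hump * entry * sqrt(taper)
  income[x >= cfg$retirement_age] <- 0
  consumption <- cfg$cons_base + cfg$cons_slope *
    pmin(pmax(x - cfg$cons_rise_start, 0), cfg$cons_cap_age - cfg$cons_rise_start)
  if (cfg$cons_old_taper < 1) {
    past <- pmax(x - cfg$cons_cap_age, 0) / (cfg$a_max - cfg$cons_cap_age)
    consumption <- consumption * (1 - (1 - cfg$cons_old_taper) * past)
  }
  if (cfg$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(cfg$seed)
    income <- income * exp(stats::rnorm(length(x), 0, cfg$noise_sd))
    consumption <- consumption * exp(stats::rnorm(length(x), 0, cfg$noise_sd))
  }
  economic_profile(income = income, consumption = consumption, ages = x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Generate an aged population pyramid
#'
#' Mixture of Gaussian bumps over age, scaled to the requested total with
#' integer rounding; any rounding residual is assigned to the modal age so
#' counts conserve the total exactly.
#'
#' @param cfg A [synth_config].
#' @param total Total population (persons), default 125 million.
#' @return A [population_distribution].
#' @export
generate_population <- function(cfg = synth_config(), total = 1.25e8) {
  stopifnot(inherits(cfg, "synth_config"))
  if (total <= 0) abort("total must be positive",
                        class = "qalyvsl_validation_error")
  x <- 0:cfg$a_max
  dens <- rep(0, length(x))
  for (i in seq_along(cfg$pyramid_modes)) {
    dens <- dens + cfg$pyramid_weights[i] *
      exp(-((x - cfg$pyramid_modes[i])^2) / (2 * cfg$pyramid_spreads[i]^2))
  }
  counts <- round(total * dens / sum(dens))
  resid <- total - sum(counts)
  counts[which.max(counts)] <- counts[which.max(counts)] + resid
  population_distribution(age = x, count = counts)
}

#' Complete Japan-like synthetic input set
#'
#' Bundles [generate_life_table()], [generate_profiles()] and
#' [generate_population()] under one configuration — the shipped preset on
#' which the package's qualitative reproduction properties are asserted.
#'
#' @param cfg A [synth_config].
#' @param total Total population.
#' @return List with elements `table`, `profile`, `pop`, `cfg`.
#' @export
japan_like_inputs <- function(cfg = synth_config(), total = 1.25e8) {
  list(table = generate_life_table(cfg),
       profile = generate_profiles(cfg),
       pop = generate_population(cfg, total = total),
       cfg = cfg)
}

#' Materialise a fixture directory of synthetic CSV inputs
#'
#' Writes `life_table.csv` (age, lx), `income.csv` and `consumption.csv`
#' (age, value), and `population.csv` (age, count) — exactly the dialects
#' the readers consume.
#'
#' @param cfg A [synth_config].
#' @param dir Output directory (created if needed).
#' @param total Total population.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(cfg = synth_config(), dir, total = 1.25e8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inp <- japan_like_inputs(cfg, total = total)
  write_curve_csv(inp$table, file.path(dir, "life_table.csv"))
  write_curve_csv(tibble::tibble(age = inp$profile$age,
                                 value = inp$profile$full_income),
                  file.path(dir, "income.csv"))
  write_curve_csv(tibble::tibble(age = inp$profile$age,
                                 value = inp$profile$full_consumption),
                  file.path(dir, "consumption.csv"))
  write_curve_csv(inp$pop, file.path(dir, "population.csv"))
  invisible(dir)
}
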