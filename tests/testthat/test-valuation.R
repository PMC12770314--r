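test_that("discount factors match their definitions and bounds", {
  ex <- discount_spec("exponential", rate = 0.01)
  hy <- discount_spec("hyperbolic", kappa = 0.01)
  expect_equal(discount_factor(40, 40, ex), 1)
  expect_equal(discount_factor(40, 40, hy), 1)
  expect_equal(discount_factor(140, 40, hy), 0.5)
  t <- seq(41, 140, by = 7)
  expect_true(all(discount_factor(t, 40, hy) >= discount_factor(t, 40, ex)))
  expect_error(discount_factor(39, 40, ex), class = "qalyvsl_domain_error")
})

test_that("VSL matches an explicit discrete-sum oracle on a toy instance", {
  lt <- toy_table(c(1, 0.5, 0.25))
  prof <- const_flow_profile(10, a_max = 2)
  traj <- full_health(2)
  u <- any_utility()
  d0 <- discount_spec(rate = 0)
  vc <- vsl_curve(lt, prof, u, traj, d0, a = 0)
  oracle <- trapz_oracle(0:2, 10 * c(1, 0.5, 0.25))
  expect_equal(attr(vc, "vsl"), oracle, tolerance = 1e-12)
  expect_equal(sum(vc$vsl_year), attr(vc, "vsl"), tolerance = 1e-12)
  # with discounting
  d <- discount_spec(rate = 0.05)
  vc2 <- vsl_curve(lt, prof, u, traj, d, a = 0)
  oracle2 <- trapz_oracle(0:2, exp(-0.05 * (0:2)) * 10 * c(1, 0.5, 0.25))
  expect_equal(attr(vc2, "vsl"), oracle2, tolerance = 1e-12)
  # anchored mid-grid: survival renormalises
  vc3 <- vsl_curve(lt, prof, u, traj, d0, a = 1)
  expect_equal(attr(vc3, "vsl"), trapz_oracle(1:2, 10 * c(1, 0.5)),
               tolerance = 1e-12)
})

test_that("a constant flow over a rectangular survival gives flow times years", {
  # l = 1 on 0..T then a linear fall to 0 in one year
  T_ <- 20
  lt <- life_table(age = 0:(T_ + 1), lx = c(rep(1, T_ + 1), 0))
  prof <- const_flow_profile(3, a_max = T_ + 1)
  vc <- vsl_curve(lt, prof, any_utility(), full_health(T_ + 1),
                  discount_spec(rate = 0), a = 0)
  expect_equal(attr(vc, "vsl"), 3 * (T_ + 0.5), tolerance = 1e-12)
})

test_that("LEV matches its discrete-sum oracle and the unit-area identity", {
  u <- any_utility()
  d0 <- discount_spec(rate = 0)
  # closing table: survival reaches 0 inside the grid
  lt <- toy_table(c(1, 0.5, 0))
  prof <- const_flow_profile(7, a_max = 2)
  traj <- full_health(2)
  # r = 0, H = 1, constant flow: the shifted-survival increment has unit
  # area, so LEV equals the flow exactly
  expect_equal(lev_value(lt, prof, u, traj, d0, a = 0), 7, tolerance = 1e-12)
  expect_equal(lev_value(lt, prof, u, traj, d0, a = 1), 7, tolerance = 1e-12)

  # discounted hand-rolled sum on the same instance, integral over [a, 3]
  r <- 0.04
  d <- discount_spec(rate = r)
  t <- 0:3
  s_now <- c(1, 0.5, 0, 0)
  s_lag <- c(1, 1, 0.5, 0)
  g <- exp(-r * t) * 7 * (s_lag - s_now)
  expect_equal(lev_value(lt, prof, u, traj, d, a = 0), trapz_oracle(t, g),
               tolerance = 1e-12)
})

test_that("LEV of a sharp survival drop approaches the closed form", {
  T_ <- 10
  lt <- life_table(age = 0:(T_ + 1), lx = c(rep(1, T_ + 1), 0))
  prof <- const_flow_profile(5, a_max = T_ + 1)
  r <- 0.05
  got <- lev_value(lt, prof, any_utility(), full_health(T_ + 1),
                   discount_spec(rate = r), a = 0, refine = 8)
  # survivorship falls linearly over [T, T+1], so the death mass is the
  # triangular unit kernel on [T, T+2]
  tri <- function(t) pmax(0, 1 - abs(t - (T_ + 1)))
  tt <- seq(0, T_ + 2, by = 1 / 64)
  closed <- trapz_oracle(tt, 5 * exp(-r * tt) * tri(tt))
  expect_equal(got, closed, tolerance = 1e-3)
})

test_that("valuation is linear in money for a fixed elasticity series", {
  inp <- japan_like_inputs()
  scen <- build_trajectory(scn_preset("SCN1"))
  u1 <- utility_family("crra", eta = 0.8, z0 = 0.3)
  u2 <- utility_family("crra", eta = 0.8, z0 = 0.6)  # doubled reference
  prof2 <- economic_profile(income = 2 * inp$profile$full_income,
                            consumption = 2 * inp$profile$full_consumption,
                            ages = inp$profile$age)
  v1 <- attr(vsl_curve(inp$table, inp$profile, u1, scen), "vsl")
  v2 <- attr(vsl_curve(inp$table, prof2, u2, scen), "vsl")
  expect_equal(v2, 2 * v1, tolerance = 1e-9)
})

test_that("halving the quadrature step barely moves VSL and LEV", {
  run <- preset_run()
  a <- 40
  v1 <- attr(vsl_curve(run$inp$table, run$inp$profile, run$utility,
                       run$scen$SCN1, a = a), "vsl")
  v2 <- attr(vsl_curve(run$inp$table, run$inp$profile, run$utility,
                       run$scen$SCN1, a = a, refine = 2), "vsl")
  expect_lt(abs(v2 - v1) / v1, 1e-3)
  l1 <- lev_value(run$inp$table, run$inp$profile, run$utility,
                  run$scen$SCN1, a = a)
  l2 <- lev_value(run$inp$table, run$inp$profile, run$utility,
                  run$scen$SCN1, a = a, refine = 2)
  expect_lt(abs(l2 - l1) / l1, 1e-3)
})

test_that("QALY normalises LEV by current QoL and fails beyond terminal age", {
  traj <- build_trajectory(scn_preset("SCN1", "linear"))
  expect_equal(qaly_value(2.0, traj, a = 30), 2.0)    # H = 1
  expect_equal(qaly_value(2.0, traj, a = 75), 4.0)    # H = 0.5
  expect_error(qaly_value(2.0, traj, a = 105),
               class = "qalyvsl_undefined_age_error")
  expect_error(qaly_value(2.0, traj, a = 30.5), class = "qalyvsl_domain_error")
})

test_that("population weighting reduces to the weighted mean", {
  qaly <- tibble::tibble(age = c(0, 1), qaly = c(4, 8))
  pop <- population_distribution(c(0, 1), c(1, 3))
  expect_equal(population_weighted_qaly(qaly, pop, age_range = c(0, Inf)), 7)
  # constant curve, any weights
  qc <- tibble::tibble(age = 0:10, qaly = rep(2.5, 11))
  pu <- population_distribution(0:10, rep(7, 11))
  expect_equal(population_weighted_qaly(qc, pu, age_range = c(0, Inf)), 2.5)
  expect_error(population_weighted_qaly(qaly, pop, age_range = c(50, 60)),
               class = "qalyvsl_validation_error")
})

test_that("population weighting matches a brute-force loop on the preset", {
  run <- preset_run()
  q <- dplyr::filter(run$res$curves, scenario == "SCN1")[, c("age", "qaly")]
  got <- population_weighted_qaly(q, run$inp$pop, age_range = c(20, Inf))
  total <- 0; wsum <- 0
  for (i in seq_len(nrow(q))) {
    a <- q$age[i]
    if (a < 20 || is.na(q$qaly[i])) next
    n <- run$inp$pop$count[run$inp$pop$age == a]
    total <- total + n * q$qaly[i]
    wsum <- wsum + n
  }
  expect_equal(got, total / wsum, tolerance = 1e-12)
})

test_that("inputs on different grids are rejected", {
  lt <- toy_table(c(1, 0.5, 0.25))
  prof <- const_flow_profile(1, a_max = 5)
  traj <- full_health(3)
  expect_error(vsl_curve(lt, prof, any_utility(), traj),
               class = "qalyvsl_validation_error")
})
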