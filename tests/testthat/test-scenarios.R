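test_that("multiplicative decline follows the annual recursion", {
  h <- build_trajectory(scn_preset("SCN1"))
  expect_equal(h$qol[h$age == 50], 1)
  expect_equal(h$qol[h$age == 51], 0.98)
  expect_equal(h$qol[h$age == 60], 0.98^10)
  expect_equal(h$qol[h$age <= 50], rep(1, 51))
})

test_that("plateaus hold the trajectory constant", {
  h <- build_trajectory(scn_preset("SCN3"))
  expect_equal(h$qol[h$age == 50], 0.99^20)
  expect_equal(h$qol[h$age == 69], h$qol[h$age == 50])
  expect_equal(h$qol[h$age == 70], h$qol[h$age == 50])
  expect_equal(h$qol[h$age == 71], h$qol[h$age == 50] * 0.99)
})

test_that("linear decline subtracts a fixed step and clips at zero", {
  h <- build_trajectory(scn_preset("SCN1", "linear"))
  expect_equal(h$qol[h$age == 75], 1 - 0.02 * 25)
  expect_equal(h$qol[h$age == 100], 0)
  expect_true(all(h$qol[h$age > 100] == 0))
})

test_that("the shock drops QoL to the configured level and then declines", {
  h <- build_trajectory(scn_preset("SCN4", shock_level = 0.8))
  expect_equal(h$qol[h$age == 59], 1)
  expect_equal(h$qol[h$age == 60], 0.8)
  expect_equal(h$qol[h$age == 61], 0.8 * 0.99)
  expect_error(
    build_trajectory(scenario_spec("bad", tibble::tibble(start_age = 30,
                                                         rate = 0.05),
                                   shock = c(60, 0.9))),
    class = "qalyvsl_validation_error")
})

test_that("trajectory areas match simple geometry", {
  # rectangle: full health to 100, zero after
  spec <- scenario_spec("rect", tibble::tibble(start_age = 100, rate = 0),
                        terminal_age = 100)
  expect_equal(trajectory_area(build_trajectory(spec, a_max = 110)), 100)
  # SCN1 linear: unit plateau to 50 plus a triangle of height 1, base 50
  h_lin <- build_trajectory(scn_preset("SCN1", "linear"))
  expect_equal(trajectory_area(h_lin), 75)
  # SCN1 multiplicative: geometric decay, checked against an independent
  # trapezoid sum and the continuous-decay closed form
  h_mul <- build_trajectory(scn_preset("SCN1"))
  expect_equal(trajectory_area(h_mul), trapz_oracle(h_mul$age, h_mul$qol),
               tolerance = 1e-12)
  closed <- 50 + (1 - 0.98^60) / (-log(0.98))
  expect_equal(trajectory_area(h_mul), closed, tolerance = 2e-5)
})

test_that("the terminal-age solver reproduces the quadratic-formula oracle", {
  # SCN2 linear: area(tau) = 50 + x - x^2/200 with x = tau - 50; solving
  # area = 75 gives x = 100 - sqrt(5000)
  spec <- solve_terminal_age(scn_preset("SCN2", "linear"), target_area = 75)
  expect_equal(spec$terminal_age, 50 + 100 - sqrt(5000), tolerance = 1e-4)
  traj <- build_trajectory(spec)
  expect_equal(trajectory_area(traj), 75, tolerance = 1e-6)
  expect_equal(traj$qol[traj$age == 80], 0)
})

test_that("the solver is idempotent on the reference scenario", {
  target <- trajectory_area(build_trajectory(scn_preset("SCN1")))
  spec <- solve_terminal_age(scn_preset("SCN1"), target)
  expect_equal(trajectory_area(build_trajectory(spec)), target,
               tolerance = 1e-6)
})

test_that("the solver matches a brute-force truncation scan", {
  target <- trajectory_area(build_trajectory(scn_preset("SCN1")))
  spec <- solve_terminal_age(scn_preset("SCN2"), target)
  # brute force: scan truncation ages, coarse then refined, for the best
  # area match
  h <- attr(build_trajectory(scn_preset("SCN2")), "untruncated")
  area_of <- function(tau) {
    k <- floor(tau); frac <- tau - k
    base <- sum((h[1:k] + h[2:(k + 1)]) / 2)
    base + frac * h[k + 1] + frac^2 / 2 * (h[k + 2] - h[k + 1])
  }
  coarse <- seq(50, 109.99, by = 1e-2)
  best <- coarse[which.min(abs(vapply(coarse, area_of, numeric(1)) - target))]
  fine <- seq(best - 0.05, best + 0.05, by = 1e-5)
  best <- fine[which.min(abs(vapply(fine, area_of, numeric(1)) - target))]
  expect_lt(abs(spec$terminal_age - best), 1e-4)
})

test_that("equal-area construction matches all scenarios to SCN1 in both modes", {
  for (mode in c("multiplicative", "linear")) {
    scen <- equal_area_scenarios(mode)
    areas <- vapply(scen, trajectory_area, numeric(1))
    expect_true(all(abs(areas - areas["SCN1"]) <= 1e-6),
                info = mode)
    # monotone beyond the first decline age
    for (nm in names(scen)) {
      first <- min(attr(scen[[nm]], "spec")$segments$start_age)
      if (!is.null(attr(scen[[nm]], "spec")$shock)) {
        first <- min(first, attr(scen[[nm]], "spec")$shock[1])
      }
      q <- scen[[nm]]$qol[scen[[nm]]$age >= first]
      expect_true(all(diff(q) <= 1e-12), info = nm)
    }
  }
})

test_that("an unreachable target area raises an infeasible-spec error", {
  expect_error(solve_terminal_age(scn_preset("SCN2"), target_area = 200),
               class = "qalyvsl_infeasible_error")
})

test_that("trajectory construction is deterministic", {
  a <- build_trajectory(scn_preset("SCN3"))
  b <- build_trajectory(scn_preset("SCN3"))
  expect_identical(a$qol, b$qol)
})
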