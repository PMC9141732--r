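test_that("GM(1,1) reproduces constant and geometric series", {
  m <- gm11_fit(c(5, 5, 5, 5))
  expect_equal(gm11_forecast(m, 3), rep(5, 3), tolerance = 1e-6)
  # exact exponential data: next term of 2,4,8,16
  m2 <- gm11_fit(c(2, 4, 8, 16))
  expect_equal(gm11_forecast(m2, 1), 32, tolerance = 32 * 1e-3)
  # fitted value at index 1 equals the observation, by construction
  m3 <- gm11_fit(c(3, 7, 6, 9, 12))
  expect_equal(m3$fitted[1], 3)
  expect_error(gm11_fit(c(1, 2, 3)), "at least 4")
  expect_error(gm11_fit(c(1, -2, 3, 4)), "positive")
})

test_that("constraint constants carry the published planning bounds", {
  cons <- build_constraints("epd")
  expect_equal(cons$total, 3405150)
  expect_equal(unname(cons$lower[["water"]]), 129512.55)
  expect_equal(unname(cons$upper[["water"]]), 131892.00)
  expect_equal(unname(cons$lower[["farmland"]]), 732848.78)
  # population constraint implies a construction-land cap of P / M
  expect_equal(cons$pop$P / cons$pop$M, 74524.8666, tolerance = 1e-7)
  # the bound box is feasible: lower bounds leave slack under the total
  expect_lt(sum(cons$lower), cons$total)
  expect_error(build_constraints("nd"), "arg")
})

test_that("ecological-priority optimum fills water and woodland", {
  sol <- solve_epd()
  expect_equal(sum(sol$x), 3405150)
  cons <- build_constraints("epd")
  expect_equal(unname(sol$x[["water"]]), unname(cons$upper[["water"]]))
  expect_equal(unname(sol$x[["farmland"]]), unname(cons$lower[["farmland"]]))
  expect_equal(unname(sol$x[["grassland"]]), unname(cons$lower[["grassland"]]))
  expect_equal(unname(sol$x[["construction"]]), unname(cons$lower[["construction"]]))
  expect_equal(unname(sol$x[["unused"]]), unname(cons$lower[["unused"]]))
  # woodland absorbs the slack
  expect_equal(unname(sol$x[["woodland"]]), 88925.66, tolerance = 0.01)
  # no constraint violated
  aud <- check_feasibility(sol$x, cons, tol = 1e-6)
  expect_false(any(aud$violated))
})

test_that("the LP optimum agrees with an independent simplex solver", {
  skip_if_not_installed("boot")
  cons <- build_constraints("epd")
  obj <- objective_spec()
  s <- simplex_oracle(obj$c, cons)
  expect_equal(s$solved, 1)
  expect_equal(unname(solve_epd()$x), unname(s$x), tolerance = 1e-6)
  # and for the pure economic objective
  s2 <- simplex_oracle(obj$d, cons)
  e0 <- solve_eed(w = 0)
  expect_equal(s2$solved, 1)
  expect_equal(sum(obj$d * e0$x), s2$value, tolerance = 1e-6)
})

test_that("capping woodland moves the slack to grassland", {
  cons <- build_constraints("epd")
  cons$upper[["woodland"]] <- cons$lower[["woodland"]]
  sol <- lp_solve_vertex(objective_spec()$c, cons)
  # grassland has the next-best ecological coefficient after water/woodland
  expect_gt(unname(sol$x[["grassland"]]), unname(cons$lower[["grassland"]]))
  expect_equal(unname(sol$x[["woodland"]]), unname(cons$lower[["woodland"]]))
})

test_that("infeasible totals are reported as such", {
  cons <- build_constraints("epd")
  cons$total <- sum(cons$lower) - 1000
  expect_error(lp_solve_vertex(objective_spec()$c, cons), "lower bounds")
})

test_that("balanced-scenario scalarization behaves at its limits", {
  epd <- solve_epd()
  e1 <- solve_eed(w = 1)
  expect_equal(unname(e1$x), unname(epd$x), tolerance = 1e-6)
  # pure economic weight drives construction to the population cap
  e0 <- solve_eed(w = 0)
  cons <- build_constraints("eed")
  expect_equal(unname(e0$x[["construction"]]), cons$pop$P / cons$pop$M,
               tolerance = 1e-6)
  expect_error(solve_eed(w = 1.5))
})

test_that("the Pareto sweep trades the objectives monotonically", {
  sw <- pareto_sweep(seq(0, 1, by = 0.2))
  # as the ecological weight rises, f1 rises and f2 falls (weakly)
  expect_true(all(diff(sw$f1) >= -1e-6))
  expect_true(all(diff(sw$f2) <= 1e-6))
})

test_that("the feasibility auditor matches hand arithmetic", {
  cons <- build_constraints("epd")
  # zero vector: misses the total-land equality by the full basin area
  z <- check_feasibility(rep(0, 6), cons)
  tot <- z[z$row == "total_land", ]
  expect_true(tot$violated)
  expect_equal(tot$slack, 3405150)
  # published EPD row: exactly one bound violation — water, 378 ha over
  epd <- check_feasibility(basin_areas("epd")$area_ha, cons)
  bad <- epd[epd$violated, ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$row, "upper_water")
  expect_equal(bad$slack, -378)
  # published 2020 row: farmland/woodland/grassland/unused rows audit clean
  a2020 <- check_feasibility(basin_areas("2020")$area_ha, cons)
  clean <- c("upper_farmland", "lower_farmland", "lower_woodland",
             "upper_grassland", "lower_grassland", "upper_unused",
             "lower_unused")
  expect_false(any(a2020$violated[a2020$row %in% clean]))
  # water and construction 2030 floors exceed the 2020 stocks by arithmetic
  expect_equal(a2020$slack[a2020$row == "lower_construction"],
               -(56888.94 - 54270))
})

test_that("service-value floor rows reproduce the 2020 valuation rows", {
  # the water-related floor row, evaluated at the 2020 areas in 10^4 CNY,
  # equals the published 2020 water-conservation value
  cons <- build_constraints("epd")
  a <- basin_areas("2020")$area_ha
  lhs <- sum(cons$service$water_related$coef * a)
  expect_equal(lhs / 1e4, 37.14, tolerance = 0.011)
  # the soil-formation floor (printed coefficients differ slightly from the
  # valuation table) is satisfied with margin at the 2020 areas
  lhs2 <- sum(cons$service$soil_formation$coef * a)
  expect_gt(lhs2, cons$service$soil_formation$rhs)
  expect_equal(lhs2 / 1e4, 18.05, tolerance = 0.35)
})
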