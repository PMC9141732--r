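# Grey multi-objective land-use structure optimization: scenario objective
# coefficients, the published constraint system for the 2030 basin, an exact
# vertex-enumeration LP solver, scenario solvers (ecological priority and
# weighted ecological-economic), and a feasibility auditor.

#' Scenario objective coefficients
#'
#' Benefit coefficients per hectare in 10^4 CNY/ha for the six land-use
#' classes: `c` the ESV benefit (the column sums of the coefficient table in
#' 10^4 CNY), `d` the 2030 economic benefit (GM(1,1) projections of
#' per-hectare land economics), and the analytic-hierarchy-process weight
#' vector retained as provenance only (not used in the optimization).
#'
#' @return list with `c`, `d`, `ahp_weights`, each named length-6.
#' @export
objective_spec <- function() {
  nm <- lulc_classes()
  list(
    c = stats::setNames(c(0.5427, 2.4500, 1.1617, 6.0942, 0.0011, 0.0577), nm),
    d = stats::setNames(c(3.5365, 0.6060, 1.6127, 1.0132, 19.1502, 0.0011), nm),
    ahp_weights = stats::setNames(
      c(0.3239, 0.0555, 0.1477, 0.0928, 1.7539, 0.0001), nm))
}

#' The published 2030 constraint system
#'
#' Total land 3,405,150 ha (equality); per-class bounds from planning policy
#' ("withdraw land and reduce water", returning farmland to woodland and
#' grassland, town-system plans, Markov-derived water and unused-land
#' limits); a construction-land population constraint `M * X5 <= P` with
#' GM(1,1)-forecast density M = 13.5825 and population P = 1,012,234; and
#' three service-value floors (water-related provisioning/regulating, soil
#' formation, biodiversity rows) in 10^4 CNY.
#'
#' @param scenario `"epd"` or `"eed"` (the natural-development scenario is a
#'   Markov projection, not an LP).
#' @return a `constraint_set`: list with `total`, `lower`, `upper`,
#'   `pop` (M, P), `service` (list of `coef`, `rhs`), `scenario`.
#' @export
build_constraints <- function(scenario = c("epd", "eed")) {
  scenario <- match.arg(scenario)
  nm <- lulc_classes()
  structure(list(
    scenario = scenario,
    total = 3405150,
    lower = stats::setNames(
      c(732848.78, 45551.59, 966377.47, 129512.55, 56888.94, 1428217.15), nm),
    upper = stats::setNames(
      c(780448.78, Inf, 1128115.56, 131892.00, Inf, 1453609.70), nm),
    pop = list(M = 13.5825, P = 1012234),
    service = list(
      water_related = list(
        coef = c(0.0673, 0.3588, 0.0897, 2.0116, 0, 0.0034), rhs = 371430),
      soil_formation = list(
        coef = c(0.0011, 0.4373, 0.1514, 0.0964, 0, 0.0043), rhs = 180450),
      biodiversity = list(
        coef = c(0.0235, 0.3655, 0.1503, 0.2803, 0, 0.0381), rhs = 26505))),
    class = "constraint_set")
}

# Assemble the constraint set as (Aeq x = beq, Aub x <= bub) with row labels.
constraint_rows <- function(cons) {
  A <- NULL; b <- NULL; lab <- NULL
  add <- function(row, rhs, label) {
    A <<- rbind(A, row); b <<- c(b, rhs); lab <<- c(lab, label)
  }
  for (j in 1:6) {
    e <- rep(0, 6); e[j] <- 1
    if (is.finite(cons$upper[j]))
      add(e, cons$upper[[j]], paste0("upper_", lulc_classes()[j]))
    add(-e, -cons$lower[[j]], paste0("lower_", lulc_classes()[j]))
  }
  pop <- rep(0, 6); pop[5] <- cons$pop$M
  add(pop, cons$pop$P, "population")
  for (nm in names(cons$service))
    add(-cons$service[[nm]]$coef, -cons$service[[nm]]$rhs,
        paste0("service_", nm))
  list(Aub = A, bub = b, labels = lab,
       Aeq = matrix(1, 1, 6), beq = cons$total)
}

#' Exact LP solve by vertex enumeration
#'
#' Maximizes `obj . x` over the six-variable polytope defined by a
#' [build_constraints()] set. Every basic solution (the total-land equality
#' plus five active inequality rows) is enumerated and solved exactly; the
#' feasible vertex with the largest objective wins, with ties broken
#' lexicographically by class order (smallest X1, then X2, ...). With ~15
#' rows this is a few thousand 6x6 solves — exact and fast, with no
#' dependence on a floating-point pivoting path.
#'
#' @param obj length-6 objective coefficient vector (maximized).
#' @param cons a `constraint_set`.
#' @param tol feasibility tolerance in ha (default 1e-6).
#' @return list with `x` (named ha vector), `value`, `active` (labels of
#'   binding rows), or an error describing infeasibility.
#' @export
lp_solve_vertex <- function(obj, cons, tol = 1e-6) {
  rows <- constraint_rows(cons)
  m <- nrow(rows$Aub)
  best <- NULL
  combos <- utils::combn(m, 5)
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    A <- rbind(rows$Aeq, rows$Aub[idx, , drop = FALSE])
    b <- c(rows$beq, rows$bub[idx])
    x <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(x)) next
    slack <- rows$bub - drop(rows$Aub %*% x)
    if (any(slack < -tol)) next
    val <- sum(obj * x)
    if (is.null(best) || val > best$value + tol ||
        (val > best$value - tol && lex_less(x, best$x))) {
      best <- list(x = x, value = val, idx = idx)
    }
  }
  if (is.null(best)) {
    viol <- infeasibility_certificate(cons, tol)
    stop("LP infeasible: ", viol)
  }
  x <- stats::setNames(best$x, lulc_classes())
  slack <- rows$bub - drop(rows$Aub %*% x)
  list(x = x, value = best$value,
       active = rows$labels[abs(slack) <= 1e-6 * pmax(1, abs(rows$bub))])
}

lex_less <- function(a, b, tol = 1e-6) {
  for (j in seq_along(a)) {
    if (a[j] < b[j] - tol) return(TRUE)
    if (a[j] > b[j] + tol) return(FALSE)
  }
  FALSE
}

# Name obviously violated structure when no vertex is feasible.
infeasibility_certificate <- function(cons, tol) {
  lo <- sum(cons$lower)
  hi <- sum(pmin(cons$upper, cons$total))
  if (lo > cons$total + tol)
    return(sprintf("sum of lower bounds %.2f exceeds total land %.2f",
                   lo, cons$total))
  if (hi < cons$total - tol)
    return(sprintf("sum of upper bounds %.2f below total land %.2f",
                   hi, cons$total))
  "no feasible vertex found"
}

#' Ecological-priority (EPD) scenario optimum
#'
#' Maximizes the total ecosystem-service value `sum(c_j X_j)` over the
#' constraint polytope.
#'
#' @param cons a `constraint_set` (default [build_constraints("epd")]).
#' @param obj an [objective_spec()].
#' @return a `scenario_solution`: list with `scenario`, `x` (ha),
#'   `areas` ([area_table]), `f1`, `f2` (10^4 CNY), `active` binding rows.
#' @export
solve_epd <- function(cons = build_constraints("epd"), obj = objective_spec()) {
  sol <- lp_solve_vertex(obj$c, cons)
  scenario_solution("EPD", sol, obj)
}

#' Balanced ecological-economic (EED) scenario optimum
#'
#' Scalarizes the bi-objective problem `max {f1, f2}` as a weighted sum of
#' min-max normalized objectives: each objective is rescaled by its range
#' over the feasible set (obtained by four auxiliary LP solves) and
#' `w * f1_hat + (1 - w) * f2_hat` is maximized; `w = 1` recovers the
#' ecological-priority optimum, `w = 0` the pure economic optimum.
#'
#' @param cons a `constraint_set` (default [build_constraints("eed")]).
#' @param obj an [objective_spec()].
#' @param w ecological weight in `[0, 1]` (default 0.5).
#' @return a `scenario_solution` (see [solve_epd()]).
#' @export
solve_eed <- function(cons = build_constraints("eed"), obj = objective_spec(),
                      w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  r1 <- objective_range(obj$c, cons)
  r2 <- objective_range(obj$d, cons)
  comb <- w * obj$c / max(r1$max - r1$min, 1e-12) +
    (1 - w) * obj$d / max(r2$max - r2$min, 1e-12)
  sol <- lp_solve_vertex(comb, cons)
  out <- scenario_solution("EED", sol, obj)
  out$w <- w
  out
}

objective_range <- function(coef, cons) {
  list(min = -lp_solve_vertex(-coef, cons)$value,
       max = lp_solve_vertex(coef, cons)$value)
}

#' Pareto sweep over the ecological weight
#'
#' @param weights grid of ecological weights.
#' @inheritParams solve_eed
#' @return data.frame with `w`, `f1`, `f2` and the six areas.
#' @export
pareto_sweep <- function(weights = seq(0, 1, by = 0.1),
                         cons = build_constraints("eed"),
                         obj = objective_spec()) {
  rows <- lapply(weights, function(w) {
    s <- solve_eed(cons, obj, w)
    c(w = w, f1 = s$f1, f2 = s$f2, s$x)
  })
  as.data.frame(do.call(rbind, rows))
}

scenario_solution <- function(label, sol, obj) {
  structure(list(
    scenario = label, x = sol$x,
    areas = area_table(sol$x, label = label),
    f1 = sum(obj$c * sol$x), f2 = sum(obj$d * sol$x),
    active = sol$active), class = "scenario_solution")
}

#' @export
print.scenario_solution <- function(x, ...) {
  cat(sprintf("%s scenario optimum (ha):\n", x$scenario))
  print(round(x$x, 2))
  cat(sprintf("f1 (ESV) = %.2f x10^4 CNY, f2 (economic) = %.2f x10^4 CNY\n",
              x$f1, x$f2))
  cat("binding rows:", paste(x$active, collapse = ", "), "\n")
  invisible(x)
}

#' Audit a land-use vector against the constraint system
#'
#' Signed slack for every constraint row (positive slack = satisfied with
#' room). Violations smaller than `tol` are treated as at-bound: the default
#' 0.5 ha is half the resolution of areas reported in km^2 at two decimals,
#' so published tables audit at their printed precision.
#'
#' @param x length-6 area vector in ha.
#' @param cons a `constraint_set`.
#' @param tol at-bound tolerance in ha (default 0.5).
#' @return data.frame with `row`, `lhs`, `bound`, `slack`, `violated`.
#' @export
check_feasibility <- function(x, cons, tol = 0.5) {
  x <- as.numeric(x)
  rows <- constraint_rows(cons)
  lhs <- drop(rows$Aub %*% x)
  slack <- rows$bub - lhs
  out <- data.frame(row = rows$labels, lhs = lhs, bound = rows$bub,
                    slack = slack, violated = slack < -tol)
  tot <- sum(x)
  # the equality row accumulates rounding from all six entries
  out <- rbind(data.frame(row = "total_land", lhs = tot, bound = cons$total,
                          slack = cons$total - tot,
                          violated = abs(tot - cons$total) > 6 * tol), out)
  rownames(out) <- NULL
  out
}
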