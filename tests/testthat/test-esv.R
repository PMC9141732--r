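test_that("farmland base value follows the 1/7 grain-revenue rule", {
  # single crop occupying all land: factors cancel to p*q/7
  expect_equal(revise_farmland_value(m = 100, p = 7, q = 1000, M = 100), 1000)
  # two crops, hand-computed: (100*2*4000 + 300*3*5000) / 400 / 7
  expect_equal(revise_farmland_value(m = c(100, 300), p = c(2, 3),
                                     q = c(4000, 5000), M = 400),
               (100 * 2 * 4000 + 300 * 3 * 5000) / 400 / 7)
  expect_equal(revise_farmland_value(numeric(0), numeric(0), numeric(0), 10), 0)
  expect_error(revise_farmland_value(1, 1, 1, 0), "positive")
})

test_that("equivalent-table scaling is linear in the base value", {
  eq <- matrix(1:54 / 10, 9, 6)
  s1 <- scale_equivalent_table(eq, E_a = 1000)
  s2 <- scale_equivalent_table(eq, E_a = 2000)
  expect_equal(s2, 2 * s1)
  expect_equal(scale_equivalent_table(eq, 1000, biomass_factor = 1),
               eq * 1000)
  expect_error(scale_equivalent_table(eq, -5), "positive")
})

test_that("coefficient column sums match the LP benefit coefficients", {
  cs <- colSums(esv_coefficients())
  expect_equal(unname(cs),
               c(5427.07, 24500.30, 11616.62, 60942.36, 11.21, 577.46),
               tolerance = 0.5 / 5000)
  # same numbers, in 10^4 CNY/ha, drive the optimizer's ecological objective
  expect_equal(unname(cs) / 1e4, unname(objective_spec()$c), tolerance = 1e-4)
})

test_that("basin totals and decompositions reproduce the published values", {
  r2020 <- compute_esv(basin_areas("2020"))
  expect_equal(format_esv(r2020$total), 238.10)
  expect_equal(format_esv(compute_esv(basin_areas("epd"))$total), 255.18)
  expect_equal(format_esv(r2020$by_service[["food_production"]]), 8.02)
  # decompositions are exact partitions of the total
  expect_equal(sum(r2020$by_service), r2020$total)
  expect_equal(sum(r2020$by_category), r2020$total)
  expect_equal(sum(r2020$by_class), r2020$total)
})

test_that("valuation is linear and zero on empty landscapes", {
  a <- basin_areas("2010")
  r1 <- compute_esv(a)
  r3 <- compute_esv(a$area_ha * 3)
  expect_equal(r3$total, 3 * r1$total)
  z <- compute_esv(rep(0, 6))
  expect_equal(z$total, 0)
  expect_true(all(z$by_service == 0))
  expect_error(compute_esv(c(-1, rep(1, 5))), "non-negative")
})

test_that("ESV change reports absolute and percent deltas", {
  a <- compute_esv(basin_areas("2020"))
  expect_equal(esv_change(a, a)$percent, 0)
  expect_equal(esv_change(a, a)$delta, 0)
  ch <- esv_change(compute_esv(basin_areas("1990")),
                   compute_esv(basin_areas("2000")))
  expect_equal(ch$percent, -2.33, tolerance = 0.01 / 2)
  zero <- compute_esv(rep(0, 6))
  expect_error(esv_change(zero, a), "zero")
})

test_that("grid valuation conserves the map total and values pure cells", {
  # uniform one-class map: every full grid cell identical
  uni <- land_raster(matrix(3L, 40, 40), cellsize = 100, nodata = 0L)
  g <- esv_raster(uni, grid_size_m = 2000)
  expect_equal(max(g$total) - min(g$total), 0)
  # one 2 km cell of pure water = 400 ha * water coefficient column sum
  water <- land_raster(matrix(4L, 20, 20), cellsize = 100, nodata = 0L)
  gw <- esv_raster(water, grid_size_m = 2000)
  expect_equal(as.numeric(gw$total), 400 * 60942.36, tolerance = 1e-6)
  # conservation against the tabular path on a mixed synthetic map
  pair <- generate_lulc_pair(small_config(seed = 31))
  gm <- esv_raster(pair$t2, grid_size_m = 800)
  expect_equal(sum(gm$total), compute_esv(pair$areas_t2)$total,
               tolerance = 1 / 1e9)
  # category layers partition the total per grid cell
  cat_sum <- gm$supplying + gm$regulating + gm$supporting + gm$cultural
  expect_equal(cat_sum, gm$total)
  expect_error(esv_raster(uni, grid_size_m = 50), "smaller")
})

test_that("natural-breaks levels match the exhaustive-search oracle", {
  x <- c(1, 2, 3, 11, 12, 13, 21, 22, 23, 100, 101, 110)
  lv <- classify_levels(x, k = 3)
  oracle <- jenks_oracle(x, 3)
  expect_equal(as.integer(lv)[order(x)], oracle$groups)
  # randomized cases against the oracle
  set.seed(42)
  for (rep in 1:5) {
    y <- round(stats::runif(14, 0, 100), 1)
    ly <- classify_levels(y, k = 4)
    oy <- jenks_oracle(y, 4)
    # compare achieved within-class SSD (partitions may tie)
    achieved <- sum(vapply(split(y, ly), function(v) sum((v - mean(v))^2),
                           numeric(1)))
    expect_equal(achieved, oy$cost, tolerance = 1e-9)
  }
})

test_that("natural-breaks levels are ordered and relabel-invariant", {
  expect_equal(as.integer(classify_levels(1:7, k = 7)), 1:7)
  x <- c(5, 1, 40, 41, 90, 91, 12)
  l1 <- as.integer(classify_levels(x, k = 3))
  l2 <- as.integer(classify_levels(x^2 + 3, k = 3))   # monotone relabeling
  expect_equal(l1, l2)
  expect_warning(classify_levels(c(1, 1, 2, 2), k = 3), "reducing k")
})

test_that("coefficient sensitivity is an ESV share with the published order", {
  # single-class landscape: CS 1 for that class, 0 elsewhere
  single <- c(0, 0, 1000, 0, 0, 0)
  s <- sensitivity_cs(area_table(single))
  expect_equal(unname(s$cs), c(0, 0, 1, 0, 0, 0))
  s2020 <- sensitivity_cs(basin_areas("2020"))
  expect_equal(s2020$ordering,
               c("grassland", "water", "farmland", "woodland", "unused",
                 "construction"))
  expect_true(all(s2020$cs < 1))
  expect_equal(sum(s2020$cs), 1)
  # sign-invariance of the perturbation
  neg <- sensitivity_cs(basin_areas("2020"), delta = -0.5)
  expect_equal(neg$cs, s2020$cs)
})
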