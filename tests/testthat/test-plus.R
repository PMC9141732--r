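test_that("neighbourhood effect counts Moore neighbours over 8", {
  # centre cell of a 3x3 all-k block has 8/8 neighbours
  m <- matrix(4L, 3, 3)
  om <- neighborhood_effect(m, 4, w_k = 0.5)
  expect_equal(om[2, 2], 8 / 8 * 0.5)
  # corner cell has 3 neighbours of 8 (border keeps denominator 8)
  expect_equal(om[1, 1], 3 / 8 * 0.5)
  # a lone k cell surrounded by others: centre sees 4 of them under rook
  m2 <- matrix(1L, 3, 3); m2[2, 2] <- 2L
  expect_equal(neighborhood_effect(m2, 2, 1)[2, 2], 0)
  expect_equal(neighborhood_effect(m2, 2, 1)[1, 2], 1 / 8)
})

test_that("adaptive inertia follows its three cases", {
  # case 1: gap not worsening -> unchanged
  expect_equal(update_inertia(c(2, 1), G1 = c(-5, 3), G2 = c(-9, 3)), c(2, 1))
  # case 2: both negative and worsening -> scale by G2/G1
  expect_equal(update_inertia(1, G1 = -20, G2 = -10), 1 * (-10) / (-20))
  # case 3: both positive and worsening -> scale by G1/G2
  expect_equal(update_inertia(1, G1 = 20, G2 = 10), 2)
  # sign change between iterations leaves D untouched
  expect_equal(update_inertia(3, G1 = 8, G2 = -4), 3)
})

test_that("transition probabilities follow the published composition", {
  expect_equal(combined_probability(0.8, 0.25, 1.5), 0.8 * 0.25 * 1.5)
  # seed branch: no neighbours and a lucky draw below suitability
  expect_equal(seeded_probability(P = 0.8, omega = 0, D = 1, r = 0.5,
                                  u_k = 0.5), 0.8 * 0.5 * 0.5)
  # unlucky draw (r >= P) keeps the combined probability (zero here)
  expect_equal(seeded_probability(0.4, 0, 1, r = 0.9, u_k = 0.5), 0)
  # with neighbours present the branch is ignored regardless of r
  expect_equal(seeded_probability(0.4, 0.25, 2, r = 0.1, u_k = 0.5),
               0.4 * 0.25 * 2)
  expect_equal(tree_vote_probability(3, 4), 0.75)
  expect_error(tree_vote_probability(5, 4))
})

test_that("map validation reproduces hand-computed accuracy and kappa", {
  m <- matrix(sample(1:6, 400, replace = TRUE), 20, 20)
  r <- land_raster(m)
  same <- validate_maps(r, r)
  expect_equal(same$overall_accuracy, 1)
  expect_equal(same$kappa, 1)
  # hand case: confusion [[40,10],[20,30]] -> OA 0.7, kappa 0.4
  cm <- matrix(0, 6, 6)
  cm[1, 1] <- 40; cm[1, 2] <- 10; cm[2, 1] <- 20; cm[2, 2] <- 30
  k <- kappa_from_confusion(cm)
  expect_equal(k$overall_accuracy, 0.7)
  expect_equal(k$kappa, 0.4)
  # shuffling one map drives kappa towards zero
  set.seed(1)
  shuf <- land_raster(matrix(sample(m), 20, 20))
  expect_lt(abs(validate_maps(shuf, r)$kappa), 0.15)
})

test_that("expansion sampling labels exactly the observed conversions", {
  cfg <- small_config(seed = 19)
  pair <- generate_lulc_pair(cfg)
  dem <- generate_dem(cfg)
  drv <- generate_drivers(dem, pair$t1, cfg)
  # identical dates: every class static, no positive labels
  s0 <- extract_expansion_samples(pair$t1, pair$t1, drv, sample_rate = 1)
  expect_true(all(vapply(s0, function(s) s$static, logical(1))))
  expect_true(all(vapply(s0, function(s) sum(s$data$label), numeric(1)) == 0))
  # full sample: positives per class equal the observed new-k cell counts
  s1 <- extract_expansion_samples(pair$t1, pair$t2, drv, sample_rate = 1)
  v1 <- raster_values(pair$t1); v2 <- raster_values(pair$t2)
  for (k in 1:6) {
    expect_equal(sum(s1[[k]]$data$label), sum(v1 != k & v2 == k))
  }
  # seeded determinism
  s2 <- extract_expansion_samples(pair$t1, pair$t2, drv, seed = 5)
  s3 <- extract_expansion_samples(pair$t1, pair$t2, drv, seed = 5)
  expect_identical(s2, s3)
})

test_that("suitability oracle passthrough and forest surfaces are in [0,1]", {
  suit <- fit_suitability(oracle = flat_suitability(10, 10, 0.3))
  expect_equal(suit[[2]][5, 5], 0.3)
  expect_error(fit_suitability(oracle = flat_suitability(4, 4, 2)), "<= 1")

  cfg <- small_config(seed = 23)
  pair <- generate_lulc_pair(cfg)
  dem <- generate_dem(cfg)
  drv <- generate_drivers(dem, pair$t1, cfg)
  samples <- extract_expansion_samples(pair$t1, pair$t2, drv)
  rf <- fit_suitability(samples, drv, n_trees = 20)
  for (k in 1:6) {
    expect_true(all(rf[[k]] >= 0 & rf[[k]] <= 1))
    expect_equal(dim(rf[[k]]), c(64, 64))
  }
})

test_that("zero net demand leaves the map unchanged", {
  cfg <- small_config(seed = 29)
  pair <- generate_lulc_pair(cfg)
  res <- run_cars(pair$t2, flat_suitability(64, 64), pair$areas_t2)
  expect_true(res$converged)
  expect_identical(res$raster$values, pair$t2$values)
  expect_equal(nrow(res$log), 0)
})

test_that("forbidden conversions make demand unreachable, by name", {
  cfg <- small_config(seed = 29)
  pair <- generate_lulc_pair(cfg)
  dem <- pair$areas_t2$area_ha
  shift <- min(dem[1], 20 * cell_area_ha(pair$t2))
  dem[5] <- dem[5] + shift; dem[1] <- dem[1] - shift
  rules <- transition_rules(forbid = cbind(1:6, 5))
  expect_error(
    run_cars(pair$t2, flat_suitability(64, 64), dem, rules = rules),
    "construction")
})

test_that("allocation hits demand, conserves area, and grows patches", {
  cfg <- small_config(seed = 29, n = 96)
  pair <- generate_lulc_pair(cfg)
  area <- cell_area_ha(pair$t2)
  dem <- pair$areas_t2$area_ha
  add <- round(0.10 * dem[5] / area) * area    # +10 % construction
  dem[5] <- dem[5] + add
  dem[3] <- dem[3] - add
  rules <- transition_rules(forbid = cbind(4, c(1, 2, 3, 5, 6)))
  # structured suitability: construction strongly prefers the east side
  suit <- flat_suitability(96, 96)
  grad <- matrix(rep(seq(0.05, 0.95, length.out = 96), each = 96), 96, 96)
  suit[[5]] <- grad
  res <- run_cars(pair$t2, suit, dem, rules = rules,
                  params = ca_params(seed = 11))
  out <- raster_area_table(res$raster)$area_ha
  expect_true(res$converged)
  expect_true(all(abs(out - dem) <= pmax(0.01 * dem, 2 * area)))
  expect_equal(sum(out), sum(dem))
  # water was frozen by the rules
  v0 <- raster_values(pair$t2); v1 <- raster_values(res$raster)
  expect_true(all(v1[v0 == 4] == 4))
  # the aggregate demand gap never increases
  expect_true(all(diff(res$log$total_gap) <= 0))
  # allocation follows the suitability surface: converted cells sit well
  # east of the landscape average of the gradient
  newc <- v1 == 5 & v0 != 5
  expect_gt(mean(grad[newc]), mean(grad) + 0.1)
  # fixed seed reproduces the map exactly
  res2 <- run_cars(pair$t2, suit, dem, rules = rules,
                   params = ca_params(seed = 11))
  expect_identical(res$raster$values, res2$raster$values)
})

test_that("the calibrated CA recovers the held-out second date", {
  cfg <- small_config(seed = 37, n = 96)
  pair <- generate_lulc_pair(cfg)
  dem <- generate_dem(cfg)
  drv <- generate_drivers(dem, pair$t1, cfg)
  samples <- extract_expansion_samples(pair$t1, pair$t2, drv, seed = 2)
  suit <- fit_suitability(samples, drv, n_trees = 30, seed = 2)
  res <- run_cars(pair$t1, suit, pair$areas_t2,
                  params = ca_params(seed = 3))
  val <- validate_maps(res$raster, pair$t2)
  expect_gt(val$overall_accuracy, 0.85)
  expect_gt(val$kappa, 0.7)
})

test_that("demand totals inconsistent with the raster are rejected", {
  cfg <- small_config(seed = 29)
  pair <- generate_lulc_pair(cfg)
  expect_error(
    run_cars(pair$t2, flat_suitability(64, 64), pair$areas_t2$area_ha * 1.5),
    "demand total")
})
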