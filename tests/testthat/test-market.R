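test_that("optimal allocation matches exhaustive assignment search on toy worlds", {
  afts <- baseline_afts()

  # single AFT occupies every cell
  w <- toy_world_2x2()
  solo <- optimal_allocation(w, afts[1])
  expect_true(all(solo$assignment == 1L))

  # 2x2 toy grid: enumerate all 16 allocations for total production
  brute <- brute_force_best_assignment(w, afts)
  opt <- optimal_allocation(w, afts)
  expect_equal(as.integer(opt$assignment), brute$assignment)
  expect_equal(sum(opt$supply), brute$value, tolerance = 1e-12)

  # farmers take cells where food production beats recreation, rest go to
  # conservationists
  crop <- as.vector(w$capitals$crop)
  nat <- as.vector(w$capitals$natural)
  expect_equal(as.integer(opt$assignment), ifelse(crop >= nat, 1L, 2L))
})

test_that("balanced allocation maximises the smaller per-service supply", {
  set.seed(11)
  for (rep in 1:5) {
    w <- random_world(2, 2)
    afts <- baseline_afts()
    bal <- balanced_allocation(w, afts)
    brute <- brute_force_best_assignment(w, afts, value = function(sup) min(sup))
    # the weight sweep traces the convex frontier; its max-min can trail the
    # lattice optimum by at most one cell's production, and never exceeds it
    expect_lte(min(bal$supply), brute$value + 1e-12)
    max_cell <- max(w$capitals$crop, w$capitals$natural)
    expect_gte(min(bal$supply), brute$value - max_cell)
  }
})

test_that("demand calibration leaves the optimum configuration just short", {
  w <- generate_capital_grids(20, 20)
  afts <- baseline_afts()
  D <- calibrate_demand(w, afts, headroom = 0.02)
  bal <- balanced_allocation(w, afts)
  expect_equal(D, 1.02 * mean(bal$supply))
  # the optimum configuration supplies each service at less than demand
  expect_lt(bal$supply[["food"]], D)
  expect_lt(bal$supply[["recreation"]], D)

  # toy world: hand computation via the exhaustive max-min oracle
  set.seed(3)
  wt <- random_world(2, 2)
  balt <- balanced_allocation(wt, afts)
  Dt <- calibrate_demand(wt, afts, headroom = 0.05)
  expect_equal(Dt, 1.05 * mean(balt$supply))

  expect_error(calibrate_demand(w, afts, headroom = 0), "positive")
  expect_error(calibrate_demand(w, list()), "non-empty")
})

test_that("demand schedules implement the step change and regional split", {
  dyn <- demand_schedule(100, dynamic = TRUE, timesteps = 25, change_timestep = 11,
                         drop_fraction = 0.75)
  for (t in 1:11) expect_equal(demand_levels(dyn, t)$recreation, 100)
  for (t in 12:25) expect_equal(demand_levels(dyn, t)$recreation, 25)
  for (t in 1:25) expect_equal(demand_levels(dyn, t)$food, 100)

  reg <- demand_schedule(100, dynamic = FALSE, n_regions = 4, timesteps = 25)
  for (t in c(1, 13, 25)) {
    expect_equal(demand_levels(reg, t)$food, rep(25, 4))
    expect_equal(demand_levels(reg, t)$recreation, rep(25, 4))
  }

  # zero drop fraction: dynamic schedule is identical to static
  nodrop <- demand_schedule(100, dynamic = TRUE, timesteps = 25, drop_fraction = 0)
  stat <- demand_schedule(100, dynamic = FALSE, timesteps = 25)
  for (t in 1:25) expect_equal(demand_levels(nodrop, t), demand_levels(stat, t))

  expect_error(demand_schedule(100, drop_fraction = 1.5), "drop_fraction")
  expect_error(demand_schedule(-1), "non-negative")
  expect_error(demand_schedule(100, dynamic = TRUE, timesteps = 10, change_timestep = 10),
               "change_timestep")
})

test_that("supply accounting sums occupant production by scope", {
  afts <- baseline_afts()
  w <- toy_world_2x2()

  empty <- compute_supply(rep(0L, 4), w, afts)
  expect_equal(empty$global, c(food = 0, recreation = 0))

  # one conservationist on a natural-capital-1 cell
  w1 <- toy_world(crop = matrix(0.3), natural = matrix(1))
  one <- compute_supply(1L, w1, aft_presets("cons"))
  expect_equal(one$global, c(food = 0, recreation = 1))

  # three hand-placed agents on the 2x2 grid; cell order is column-major
  alloc <- c(1L, 2L, 0L, 1L)  # farmer, conservationist, empty, farmer
  sup <- compute_supply(alloc, w, afts)
  crop <- as.vector(w$capitals$crop)
  nat <- as.vector(w$capitals$natural)
  expect_equal(sup$global[["food"]], crop[1] + crop[4])
  expect_equal(sup$global[["recreation"]], nat[2])
})

test_that("global supply equals the sum of regional supplies", {
  set.seed(9)
  w <- random_world(6, 6)
  afts <- aft_presets()
  regions <- make_region_map(6, 6, 2)
  alloc <- sample(0:length(afts), 36, replace = TRUE)
  sup <- compute_supply(alloc, w, afts, regions)
  expect_equal(sup$global, colSums(sup$regional), tolerance = 1e-12)
})

test_that("unmet fraction follows the normalised-demand convention", {
  expect_equal(unmet_fraction(100, 25), 0.75)
  expect_equal(unmet_fraction(50, 50), 0)
  expect_equal(unmet_fraction(0, 123), 0)
  expect_equal(unmet_fraction(100, 150), -0.5)
  expect_error(unmet_fraction(-1, 0), ">= 0")
})

test_that("competitiveness combines benefit and production per service", {
  afts <- aft_presets(c("hif", "cons"))
  lin3 <- list(food = benefit_linear(3), recreation = benefit_linear(3))

  # zero production of every service
  expect_equal(
    competitiveness(afts$cons, c(crop = 1, natural = 0),
                    c(food = 1, recreation = 1), lin3), 0)

  # unmet food fraction 1, farmer on a full-capital cell: 3 * 1 * 1
  expect_equal(
    competitiveness(afts$hif, c(crop = 1, natural = 1),
                    c(food = 1, recreation = 0.2), lin3), 3)

  # oversupply of both services with the linear form gives zero benefit
  expect_equal(
    competitiveness(afts$hif, c(crop = 1, natural = 1),
                    c(food = -0.1, recreation = -0.5), lin3), 0)

  # exponential form stays positive whenever production is positive
  ex <- list(food = benefit_exponential(), recreation = benefit_exponential())
  expect_gt(
    competitiveness(afts$hif, c(crop = 0.05, natural = 0),
                    c(food = -2, recreation = -2), ex), 0)

  # linear competitiveness is non-decreasing in each unmet fraction
  base <- competitiveness(afts$hif, c(crop = 0.7, natural = 0.4),
                          c(food = 0.3, recreation = 0.1), lin3)
  up <- competitiveness(afts$hif, c(crop = 0.7, natural = 0.4),
                        c(food = 0.6, recreation = 0.1), lin3)
  expect_gte(up, base)
})
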