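test_that("dominance: without rotation, all land goes to the best activity", {
  sol <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                       options = list(crops = c("WW1", "WOSR"),
                                      rotation = FALSE,
                                      unconstrained_resources = TRUE))
  best <- sol$activities$activity[which.max(sol$activities$gm)]
  expect_equal(unname(sol$areas[best]), 400, tolerance = 1e-6)
  expect_equal(sum(sol$areas), 400, tolerance = 1e-6)
})

test_that("forced alternation splits the land 50/50 at the hand-computed value", {
  # only a break crop and first wheat: steady-state flows force equal areas
  sol <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                       options = list(crops = c("WW1", "WOSR"),
                                      unconstrained_resources = TRUE))
  expect_equal(unname(sol$species_area[c("WW", "WOSR")]), c(200, 200),
               tolerance = 1e-6)
  # hand computation from the coefficient table: 200 ha of the best
  # activity of each crop, no contracting
  tab <- sol$activities
  hand <- 200 * max(tab$gm[tab$crop == "WW1"]) +
    200 * max(tab$gm[tab$crop == "WOSR"])
  expect_equal(sol$gm, hand, tolerance = 1e-6)
})

test_that("LP optimum matches the brute-force grid oracle on 3-crop toys", {
  skip_if_not_installed("igraph")
  for (seed in c(1, 7)) {
    b <- random_calibration(seed)
    b$resources$area_ha <- 60  # 1 ha grid over the full simplex stays small
    crops <- c("WW1", "WB", "WOSR")
    sol <- optimize_farm(b, "SRT2", "2011", "max_GM",
                         options = list(crops = crops,
                                        unconstrained_resources = TRUE))
    oracle <- grid_oracle_gm(b, crops, "SRT2")
    expect_lt(abs(sol$gm - oracle) / abs(oracle), 0.005)
  }
})

test_that("every solution conserves land and is non-negative", {
  for (tl in all_tillages) for (ob in c("max_GM", "min_GHG")) {
    sol <- cached_solution(tl, ob)
    expect_equal(sum(sol$areas), 400, tolerance = 1e-6)
    expect_true(all(sol$areas >= -1e-9))
    expect_true(all(sol$hire$own_h >= -1e-9))
    expect_true(all(sol$hire$hire_h >= -1e-9))
  }
})

test_that("metrics are recomputable from areas times coefficients", {
  for (tl in c("CT", "ZT")) for (ob in c("max_GM", "max_NE", "min_GHG")) {
    sol <- cached_solution(tl, ob)
    tab <- sol$activities
    expect_equal(sol$ne, sum(sol$areas * tab$ne))
    expect_equal(sol$ghg, sum(sol$areas * tab$ghg))
    expect_equal(sol$gm, sum(sol$areas * tab$gm) - sol$hire_cost)
    expect_equal(sol$fuel_l, sum(sol$areas * tab$fuel_l))
  }
})

test_that("Greening caps force three species with the third at 20 ha or more", {
  for (tl in c("CT", "ZT")) for (ob in c("max_GM", "max_NE", "min_GHG")) {
    sol <- cached_solution(tl, ob, greening = TRUE)
    sp <- sort(sol$species_area[sol$species_area > 1e-6], decreasing = TRUE)
    expect_gte(length(sp), 3)
    expect_gte(sp[3], 20 - 1e-6)
    # every pair of species is within the 95% cap
    expect_lte(sp[1] + sp[2], 380 + 1e-6)
  }
})

test_that("adding Greening never improves the optimised objective", {
  cases <- list(the_bundle, random_calibration(11), random_calibration(23))
  for (b in cases) for (ob in c("max_GM", "max_NE", "min_GHG")) {
    free <- optimize_farm(b, "ZT", "2011", ob)
    green <- optimize_farm(b, "ZT", "2011", ob, options = list(greening = TRUE))
    if (ob == "min_GHG")
      expect_gte(green$objective_value, free$objective_value - 1e-6)
    else
      expect_lte(green$objective_value, free$objective_value + 1e-6)
  }
})

test_that("Greening with two available species is infeasible", {
  expect_error(
    optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                  options = list(crops = c("WW1", "WOSR"), greening = TRUE)),
    "[Gg]reening")
})

test_that("a system with component-wise fewer passes never loses gross margin", {
  # zero tillage's pass counts are dominated by both shallow systems
  for (seed in c(3, 17)) {
    b <- random_calibration(seed)
    gm_zt <- optimize_farm(b, "ZT", "2011", "max_GM")$gm
    expect_gte(gm_zt + 1e-6, optimize_farm(b, "SRT1", "2011", "max_GM")$gm)
    expect_gte(gm_zt + 1e-6, optimize_farm(b, "SRT2", "2011", "max_GM")$gm)
  }
})

test_that("solver is deterministic for a fixed programme", {
  s1 <- optimize_farm(the_bundle, "SRT2", "2011", "max_GM")
  s2 <- optimize_farm(the_bundle, "SRT2", "2011", "max_GM")
  expect_identical(s1$areas, s2$areas)
  expect_identical(s1$gm, s2$gm)
})
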