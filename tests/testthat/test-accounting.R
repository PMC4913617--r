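test_that("hourly embedded burden is weight x factor / lifespan", {
  b <- the_bundle
  en <- b$energy_factors; ef <- b$emission_factors
  m <- function(id) b$machines[b$machines$id == id, ]

  r <- machinery_hourly_embedded(m("onepass_cultivator"), en, ef)
  expect_equal(unname(r["energy_mj_h"]), 56.35)
  r <- machinery_hourly_embedded(m("springtine_harrow"), en, ef)
  expect_equal(unname(r["energy_mj_h"]), 26.83, tolerance = 1e-3)
  r <- machinery_hourly_embedded(m("medium_disc"), en, ef)
  expect_equal(unname(r["energy_mj_h"]), 13.19, tolerance = 1e-3)

  # identity: rate x lifespan = weight x per-kg factor, all machines
  for (i in seq_len(nrow(b$machines))) {
    mi <- b$machines[i, ]
    r <- machinery_hourly_embedded(mi, en, ef)
    expect_equal(r[["energy_mj_h"]] * mi$lifespan_h,
                 mi$weight_kg * en$steel_mj_kg, tolerance = 1e-9)
    expect_equal(r[["emissions_kgco2e_h"]] * mi$lifespan_h,
                 mi$weight_kg * ef$steel_kgco2e_kg, tolerance = 1e-9)
  }

  zero <- list(weight_kg = 0, lifespan_h = 3000)
  expect_equal(unname(machinery_hourly_embedded(zero, en, ef)), c(0, 0))
  bad <- list(weight_kg = 100, lifespan_h = 0)
  expect_error(machinery_hourly_embedded(bad, en, ef), "lifespan")
})

test_that("soil N2O follows the emission-factor formula", {
  f <- the_bundle$emission_factors
  # closed form with the shipped defaults (EF 1.6%, background 1.4, GWP 298)
  expect_equal(soil_n2o_co2e(0, f), 1.4 * 44 / 28 * 298, tolerance = 1e-6)
  expect_equal(soil_n2o_co2e(100, f), (1.6 + 1.4) * 44 / 28 * 298,
               tolerance = 1e-6)
  expect_equal(round(soil_n2o_co2e(0, f), 1), 655.6)
  # strictly increasing in applied N
  n <- c(0, 50, 120, 200)
  expect_true(all(diff(soil_n2o_co2e(n, f)) > 0))
  expect_error(soil_n2o_co2e(-1, f), "nitrogen")
})

test_that("establishment hours and fuel follow the pass matrix", {
  b <- the_bundle
  # ploughed wheat: 70 + 2 x 67 + 43 minutes
  r <- operation_hours_and_fuel(b, "CT", "WW1")
  expect_equal(r$total_hours * 60, 247)
  # zero tillage is the drill pass alone, for every crop
  for (cr in b$crops$id)
    expect_equal(operation_hours_and_fuel(b, "ZT", cr)$total_hours * 60, 43)
  # deep reduced tillage beans: one cultivator pass plus the drill
  r <- operation_hours_and_fuel(b, "DRT", "WFB")
  expect_equal(r$total_hours * 60, 24 + 43)
  # broadcast oilseed rape: no drill pass, hence no drill time or fuel
  r <- operation_hours_and_fuel(b, "SRT1", "WOSR")
  expect_equal(r$total_hours * 60, 2 * 42)
  expect_false("drill" %in% r$ops$op)
  expect_error(operation_hours_and_fuel(b, "CT", "MAIZE"), "unknown crop")
})

test_that("pesticide programme costs sum the printed category costs", {
  b <- the_bundle
  expect_equal(pesticide_program_cost(b, "WW1", "2014"),
               77.93 + 44.04 + 23.50 + 4.96 + 14.81)
  expect_equal(pesticide_program_cost(b, "WOSR", "2011"),
               29.14 + 89.43 + 12.87 + 20.66)
  # second wheats swap only the seed-treatment line
  expect_equal(pesticide_program_cost(b, "WW2", "2011") -
                 pesticide_program_cost(b, "WW1", "2011"), 16.09 - 14.19)
})

test_that("gross margin components behave as revenue minus fixed costs", {
  b <- the_bundle
  # zero yield: GM is minus the cost total
  a0 <- activity_coefficients(b, "WW1", "SR", 0.75, "CT", "2011",
                              yield_multiplier = 0)
  expect_equal(a0$gm, -(a0$cost_fert + a0$cost_pest + a0$cost_seed +
                          a0$cost_fuel + a0$cost_contract))
  # doubling the grain price doubles grain revenue and changes no cost
  b2 <- b
  b2$crop_prices$grain_2011 <- 2 * b2$crop_prices$grain_2011
  a1 <- activity_coefficients(b, "WB", "SR", 1, "ZT", "2011")
  a2 <- activity_coefficients(b2, "WB", "SR", 1, "ZT", "2011")
  expect_equal(a2$revenue_grain, 2 * a1$revenue_grain)
  for (col in c("cost_fert", "cost_pest", "cost_seed", "cost_fuel",
                "cost_contract", "fuel_l", "ne", "ghg"))
    expect_equal(a2[[col]], a1[[col]])
  expect_error(activity_coefficients(b, "WW1", "SR", 0.6, "CT", "2011"),
               "n_level")
})

test_that("NE and GHG accounting identities hold for every activity", {
  for (tl in all_tillages) {
    tab <- activity_table(the_bundle, tl, "2011")
    expect_equal(tab$ne, tab$energy_out - tab$energy_fert - tab$energy_pest -
                   tab$energy_seed - tab$energy_fuel - tab$energy_mach)
    expect_equal(tab$ghg, tab$ghg_n2o + tab$ghg_fert + tab$ghg_pest +
                   tab$ghg_fuel + tab$ghg_mach)
  }
})

test_that("GM is affine in a uniform yield multiplier", {
  # grain drying fuel is the only yield-proportional cost, so GM at three
  # multipliers must be collinear
  for (act in list(c("WW1", "SR", "0.75"), c("WOSR", "none", "1"),
                   c("WB", "INC", "0.5"))) {
    gm <- vapply(c(0.6, 0.8, 1.0), function(m)
      activity_coefficients(the_bundle, act[1], act[2], as.numeric(act[3]),
                            "ZT", "2011", yield_multiplier = m)$gm,
      numeric(1))
    expect_equal(gm[2], (gm[1] + gm[3]) / 2, tolerance = 1e-9)
  }
})
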