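test_that("the conventional system's own threshold is zero", {
  th <- yield_threshold(the_bundle, "CT", "GM")
  expect_equal(th$p_star, 0)
  expect_equal(th$value_at_threshold, th$baseline_value,
               tolerance = 1e-6)
})

test_that("a fixed-mix farm has the closed-form threshold (A - GM_CT)/B", {
  # restricting zero tillage to first wheat + oilseed rape pins the mix at
  # 200/200, so GM(p) = A - B p exactly and the threshold has a closed form
  opts <- list(crops = c("WW1", "WOSR"), unconstrained_resources = TRUE)
  gm_at <- function(p) optimize_farm(
    the_bundle, "ZT", "2011", "max_GM",
    options = c(opts, list(yield_multiplier = 1 - p)))$gm
  A <- gm_at(0)
  B <- (A - gm_at(0.5)) / 0.5
  gm_ct <- optimize_farm(the_bundle, "CT", "2011", "max_GM")$gm
  p_closed <- (A - gm_ct) / B
  th <- yield_threshold(the_bundle, "ZT", "GM", tillage_options = opts)
  expect_equal(th$p_star, p_closed, tolerance = 1e-4)
  expect_equal(th$value_at_threshold, th$baseline_value,
               tolerance = 1e-5 * abs(th$baseline_value))
})

test_that("bisection agrees with a 0.1%-step grid scan within 0.001", {
  opts <- list(crops = c("WW1", "WOSR"), unconstrained_resources = TRUE)
  th <- yield_threshold(the_bundle, "ZT", "GM", tillage_options = opts)
  gm_ct <- optimize_farm(the_bundle, "CT", "2011", "max_GM")$gm
  grid_p <- NA
  for (p in seq(0, 1, by = 0.001)) {
    g <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                       options = c(opts, list(yield_multiplier = 1 - p)))$gm
    if (g <= gm_ct) { grid_p <- p; break }
  }
  expect_false(is.na(grid_p))
  expect_lt(abs(th$p_star - grid_p), 0.001 + 1e-9)
})

test_that("optimised GM is nonincreasing and midpoint-convex in the penalty", {
  ps <- c(0, 0.2, 0.4, 0.6, 0.8)
  gm <- vapply(ps, function(p) optimize_farm(
    the_bundle, "ZT", "2011", "max_GM",
    options = list(yield_multiplier = 1 - p))$gm, numeric(1))
  expect_true(all(diff(gm) <= 1e-6))
  # max of affine functions of p: midpoint value never above the chord
  for (i in seq_len(length(ps) - 2))
    expect_lte(gm[i + 1], (gm[i] + gm[i + 2]) / 2 + 1e-6 * abs(gm[i]))
})

test_that("land compensation identities hold", {
  base <- cached_solution("ZT")
  # zero penalty: no extra land
  lc0 <- land_compensation(base, base, the_bundle)
  expect_equal(lc0$extra_land_frac_t, 0, tolerance = 1e-9)
  # unchanged mix at penalty p: exactly 1/(1-p) - 1
  p <- 0.142
  pen <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                       options = list(crops = c("WW1", "WOSR"),
                                      unconstrained_resources = TRUE,
                                      yield_multiplier = 1 - p))
  b0 <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                      options = list(crops = c("WW1", "WOSR"),
                                     unconstrained_resources = TRUE))
  lc <- land_compensation(pen, b0, the_bundle)
  expect_equal(lc$extra_land_frac_t, 1 / (1 - p) - 1, tolerance = 1e-9)
  expect_equal(lc$extra_land_frac_kcal, 1 / (1 - p) - 1, tolerance = 1e-9)
  # a mix shifted toward a lower-yielding crop needs strictly more land
  lc_shift <- land_compensation(pen, base, the_bundle)
  expect_gte(lc_shift$extra_land_frac_t, lc$extra_land_frac_t - 1e-9)
  # a zero-output penalised farm has no defined compensation
  zed <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                       options = list(yield_multiplier = 0))
  expect_error(land_compensation(zed, base, the_bundle), "zero")
})

test_that("weed-control addon shifts GM linearly and preserves the ZT lead", {
  # zero addon reproduces the baseline
  w0 <- weed_control_scenario(the_bundle, "ZT", herbicide_cost_ha = 0)
  expect_equal(w0$solution$gm, cached_solution("ZT")$gm, tolerance = 1e-6)
  # with the mix pinned, GM falls by exactly addon x 400
  opts <- list(crops = c("WW1", "WOSR"), unconstrained_resources = TRUE)
  g0 <- optimize_farm(the_bundle, "ZT", "2011", "max_GM", options = opts)$gm
  g1 <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                      options = c(opts, list(herbicide_addon = 42.5)))$gm
  expect_equal(g0 - g1, 42.5 * 400, tolerance = 1e-6)
  # extreme scenario: zero tillage still beats conventional tillage
  wx <- weed_control_scenario(the_bundle, "ZT", extreme = TRUE)
  expect_gt(wx$solution$gm, cached_solution("CT")$gm)
  expect_equal(wx$addon, 85)
  expect_equal(wx$net_margin$extra_machinery_cost, 4.81 * 400)
})

test_that("spring barley enters only under large penalties on other crops", {
  sw <- sb_selection_sweep(the_bundle, penalties = c(0, 0.1, 0.15, 0.2, 0.25))
  expect_equal(sw$sb_area_ha[sw$penalty <= 0.15], rep(0, 3), tolerance = 1e-6)
  expect_true(all(diff(sw$sb_area_ha) >= -1e-6))
  expect_gt(sw$sb_area_ha[sw$penalty == 0.2], 100)
  expect_equal(attr(sw, "entry_threshold"), 0.2)
  # at the 20% penalty the solution still grows wheat and oilseed rape
  ym <- stats::setNames(rep(0.8, 7), the_bundle$crops$id); ym["SB"] <- 1
  s20 <- optimize_farm(the_bundle, "ZT", "2011", "max_GM",
                       options = list(yield_multiplier = ym))
  sp <- s20$species_area[s20$species_area > 1e-6]
  expect_true(all(c("WW", "WOSR", "SB") %in% names(sp)))
})

test_that("the scenario matrix reports every combination and the deltas", {
  sm <- scenario_matrix(the_bundle, tillages = c("CT", "ZT"),
                        objectives = c("max_GM", "min_GHG"))
  expect_equal(nrow(sm$metrics), 4)
  expect_true(all(sm$metrics$status == "optimal"))
  # delta arithmetic: rounded percent change recomputed from the metrics
  gm_ct <- sm$metrics$gm[sm$metrics$tillage == "CT" &
                           sm$metrics$objective == "max_GM"]
  gm_zt <- sm$metrics$gm[sm$metrics$tillage == "ZT" &
                           sm$metrics$objective == "max_GM"]
  d <- sm$deltas[sm$deltas$tillage == "ZT" & sm$deltas$objective == "max_GM", ]
  expect_equal(d$gm_premium_pct, round(100 * (gm_zt / gm_ct - 1)))
  expect_true(d$nm_diff_gbp_ha > 0)
  # empty tillage list: empty report
  sm0 <- scenario_matrix(the_bundle, tillages = character(0))
  expect_null(sm0$metrics)
  expect_length(sm0$solutions, 0)
})
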