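# Per-hectare activity accounting: gross margin, net energy, GHG emissions,
# fuel and machine hours for crop activities under a tillage system.

# map a crop variant id to the species column used by the pass matrix,
# prices and pesticide tables
crop_species <- function(bundle, crop) {
  i <- match(crop, bundle$crops$id)
  if (is.na(i)) stop("unknown crop '", crop, "'")
  bundle$crops$species[i]
}

machine_row <- function(bundle, id) {
  i <- match(id, bundle$machines$id)
  if (is.na(i)) stop("unknown machine '", id, "'")
  bundle$machines[i, ]
}

#' Hourly embedded (indirect) energy and emissions of a machine
#'
#' Machinery is assumed to be built of steel; its manufacture burden is
#' allocated uniformly over the machine's working lifespan:
#' `weight * factor / lifespan`.
#'
#' @param machine A one-row data frame (or list) with `weight_kg` and
#'   `lifespan_h`, e.g. a row of `bundle$machines`.
#' @param energy Energy factor list with `steel_mj_kg`.
#' @param emissions Emission factor list with `steel_kgco2e_kg`.
#' @return Named numeric vector: `energy_mj_h`, `emissions_kgco2e_h`.
#' @examples
#' b <- paperlike_calibration()
#' m <- b$machines[b$machines$id == "onepass_cultivator", ]
#' machinery_hourly_embedded(m, b$energy_factors, b$emission_factors)
#' @export
machinery_hourly_embedded <- function(machine, energy, emissions) {
  if (machine$lifespan_h <= 0) stop("machine lifespan must be > 0")
  c(energy_mj_h = machine$weight_kg * energy$steel_mj_kg / machine$lifespan_h,
    emissions_kgco2e_h = machine$weight_kg * emissions$steel_kgco2e_kg /
      machine$lifespan_h)
}

#' Soil nitrous-oxide emissions in CO2-equivalents
#'
#' Direct soil N2O is modelled as a fixed fraction of applied nitrogen plus
#' a background soil emission, converted from N2O-N to N2O by mass ratio
#' 44/28 and to CO2-equivalents by the global warming potential of N2O.
#'
#' @param applied_n Applied nitrogen, kg N per hectare (>= 0).
#' @param f Emission factor list (`n2o_ef`, `n2o_background_kg_n_ha`,
#'   `n2o_mass_ratio`, `gwp_n2o`).
#' @return kg CO2-eq per hectare per year.
#' @export
soil_n2o_co2e <- function(applied_n, f) {
  if (any(applied_n < 0)) stop("applied nitrogen must be >= 0")
  (f$n2o_ef * applied_n + f$n2o_background_kg_n_ha) *
    f$n2o_mass_ratio * f$gwp_n2o
}

# establishment (tillage + drilling) operations for a crop under a system;
# one row per operation with positive passes
establishment_ops <- function(bundle, tillage, crop) {
  if (!tillage %in% bundle$tillage$id) stop("unknown tillage system '", tillage, "'")
  sp <- crop_species(bundle, crop)
  pa <- bundle$passes[bundle$passes$tillage == tillage, ]
  if (!sp %in% names(pa)) stop("crop '", crop, "' not in pass matrix")
  out <- NULL
  for (i in seq_len(nrow(pa))) {
    n_pass <- pa[[sp]][i]
    if (n_pass <= 0) next
    op <- bundle$operations[bundle$operations$id == pa$op[i], ]
    hours <- n_pass * op$work_rate_min_ha / 60
    power <- if (op$power == "self") op$implement else op$power
    fuel <- hours * machine_row(bundle, power)$fuel_l_h
    out <- rbind(out, data.frame(
      op = op$id, implement = op$implement, power = power,
      class = machine_row(bundle, power)$class,
      passes = n_pass, hours = hours, fuel_l = fuel, contract = FALSE))
  }
  out
}

#' Establishment machine hours and fuel for a crop under a tillage system
#'
#' Sums hours (work-rate minutes per pass / 60, times pass count) and
#' tractor fuel over the cultivation and drilling operations of the pass
#' matrix. Broadcast oilseed rape under the reduced-tillage systems has a
#' zero drill pass count, so no drilling time or fuel is incurred.
#'
#' @param bundle A `farm_bundle`.
#' @param tillage Tillage system id (`CT`, `RP`, `DRT`, `SRT1`, `SRT2`, `ZT`).
#' @param crop Crop variant id.
#' @return List with `ops` (per-operation detail), `hours_by_class` (named
#'   vector of machine-class hours per ha), `total_hours` and `fuel_l`.
#' @export
operation_hours_and_fuel <- function(bundle, tillage, crop) {
  ops <- establishment_ops(bundle, tillage, crop)
  if (is.null(ops))
    return(list(ops = NULL, hours_by_class = numeric(0),
                total_hours = 0, fuel_l = 0))
  hbc <- tapply(ops$hours, ops$class, sum)
  list(ops = ops, hours_by_class = c(hbc),
       total_hours = sum(ops$hours), fuel_l = sum(ops$fuel_l))
}

#' Pesticide programme cost for a crop variant
#'
#' Sums the programme category costs for the chosen price year. First
#' wheats use the first-wheat seed-treatment line; second and continuous
#' wheats the other line.
#'
#' @param bundle A `farm_bundle`.
#' @param crop Crop variant id.
#' @param year Price year, `"2011"` or `"2014"`.
#' @return Programme cost, GBP per hectare.
#' @export
pesticide_program_cost <- function(bundle, crop, year = "2011") {
  sum(pesticide_program(bundle, crop)[[paste0("cost_", year)]])
}

# programme rows applicable to a crop variant (resolves the two wheat
# seed-treatment lines)
pesticide_program <- function(bundle, crop) {
  sp <- crop_species(bundle, crop)
  pp <- bundle$pesticides[bundle$pesticides$crop == sp, ]
  if (sp == "WW") {
    keep <- if (crop == "WW1") c("all", "first") else c("all", "other")
    pp <- pp[pp$wheat_variant %in% keep, ]
  }
  pp
}

# in-season and harvest operations for a crop (identical across tillage
# systems): spraying, fertiliser spreading, combining, and the always-
# contracted swathing (oilseed rape) and baling (cereals, straw removed)
inseason_ops <- function(bundle, crop, straw) {
  ci <- bundle$crops[match(crop, bundle$crops$id), ]
  harvest_period <- if (ci$harvest == "early") "earlyautumn" else "autumn"
  rows <- list()
  add <- function(op_id, passes, period, contract = FALSE) {
    if (passes <= 0) return()
    op <- bundle$operations[bundle$operations$id == op_id, ]
    power <- if (op$power == "self") op$implement else op$power
    hours <- passes * op$work_rate_min_ha / 60
    rows[[length(rows) + 1]] <<- data.frame(
      op = op$id, implement = op$implement, power = power,
      class = machine_row(bundle, power)$class, passes = passes,
      hours = hours, fuel_l = hours * machine_row(bundle, power)$fuel_l_h,
      period = period, contract = contract)
  }
  add("spray", sum(pesticide_program(bundle, crop)$sprays), "spring")
  add("fert_spread", ci$fert_passes, "spring")
  add("combine", 1, harvest_period)
  if (ci$species == "WOSR") add("swath", 1, harvest_period, contract = TRUE)
  if (ci$category == "cereal" && identical(straw, "SR"))
    add("bale", 1, harvest_period, contract = TRUE)
  do.call(rbind, rows)
}

# enumerate the activity set: cereals x {SR, INC} x N levels; oilseed rape
# x N levels; beans (zero N) a single activity
activity_grid <- function(bundle) {
  out <- NULL
  for (i in seq_len(nrow(bundle$crops))) {
    ci <- bundle$crops[i, ]
    fates <- if (ci$category == "cereal") c("SR", "INC") else "none"
    levels <- if (ci$n_rate_kg_ha > 0) bundle$n_response$level else 1.0
    out <- rbind(out, expand.grid(crop = ci$id, straw = fates,
                                  n_level = levels,
                                  stringsAsFactors = FALSE))
  }
  out$activity <- sprintf("%s:%s:N%d", out$crop, out$straw,
                          round(out$n_level * 100))
  out
}

#' Per-hectare coefficients of one crop activity
#'
#' Computes the full gross-margin, net-energy and GHG component breakdown
#' for a crop activity (crop variant, straw fate, nitrogen level) under a
#' tillage system and price year. Gross margin is revenue (grain, plus
#' straw where baled) less fertiliser, pesticide programme, seed, fuel for
#' all operations and grain drying, and the fixed contractor fees for
#' swathing and baling. Net energy is output energy minus input manufacture
#' energy, fuel energy and hourly-allocated machinery embedded energy; GHG
#' sums input manufacture, fuel combustion, machinery embedded and soil
#' N2O components. Grain drying fuel is the only yield-proportional cost.
#'
#' @param bundle A `farm_bundle`.
#' @param crop Crop variant id.
#' @param straw `"SR"` (baled and sold), `"INC"` (incorporated) or `"none"`.
#' @param n_level Fraction of the recommended nitrogen rate (0.5, 0.75, 1).
#' @param tillage Tillage system id.
#' @param year Price year, `"2011"` or `"2014"`.
#' @param yield_multiplier Scalar, or named vector by crop id, scaling
#'   grain and straw yields (yield-penalty scenarios use `1 - p`).
#' @param herbicide_addon Extra herbicide cost, GBP per ha per year, added
#'   to variable costs (weed-control scenarios).
#' @return One-row data frame with all components and totals (`gm`, `ne`,
#'   `ghg`, `fuel_l`, `output_t`, `kcal`, ...).
#' @export
activity_coefficients <- function(bundle, crop, straw, n_level, tillage,
                                  year = "2011", yield_multiplier = 1,
                                  herbicide_addon = 0) {
  ci <- bundle$crops[match(crop, bundle$crops$id), ]
  if (is.na(ci$id)) stop("unknown crop '", crop, "'")
  pr <- bundle$prices[[year]]
  if (is.null(pr)) stop("missing price set for year '", year, "'")
  cp <- bundle$crop_prices[match(ci$species, bundle$crop_prices$crop), ]
  grain_price <- cp[[paste0("grain_", year)]]
  if (is.na(grain_price)) stop("missing price: grain price for ", ci$species)

  ymult <- if (length(yield_multiplier) > 1) {
    if (is.na(yield_multiplier[crop])) 1 else unname(yield_multiplier[crop])
  } else yield_multiplier
  nmult <- bundle$n_response$multiplier[match(n_level, bundle$n_response$level)]
  if (is.na(nmult)) stop("n_level must be one of ",
                         paste(bundle$n_response$level, collapse = ", "))

  grain_t <- ci$grain_yield_t_ha * nmult * ymult
  straw_t <- if (identical(straw, "SR")) ci$straw_yield_t_ha * nmult * ymult else 0
  if (identical(straw, "SR")) {
    straw_price <- cp[[paste0("straw_", year)]]
    if (is.na(straw_price)) stop("missing price: straw price for ", ci$species)
  } else straw_price <- 0

  applied_n <- n_level * ci$n_rate_kg_ha
  fert <- pr$fert_gbp_kg
  cost_fert <- applied_n * fert$N + ci$p_rate_kg_ha * fert$P +
    ci$k_rate_kg_ha * fert$K
  cost_pest <- pesticide_program_cost(bundle, crop, year)
  cost_seed <- ci[[paste0("seed_cost_", year)]]

  est <- establishment_ops(bundle, tillage, crop)
  ins <- inseason_ops(bundle, crop, straw)
  if (!is.null(est)) est$period <- NA_character_
  ops <- rbind(est, ins)

  drying_l <- grain_t * ci$drying_fuel_l_t
  fuel_l <- sum(ops$fuel_l) + drying_l
  cost_fuel <- fuel_l * pr$fuel_gbp_l

  contract <- ops[ops$contract, , drop = FALSE]
  cost_contract <- if (nrow(contract))
    sum(contract$hours * vapply(contract$power, contractor_fee,
                                numeric(1), bundle = bundle, year = year))
  else 0

  revenue_grain <- grain_t * grain_price
  revenue_straw <- straw_t * straw_price
  gm <- revenue_grain + revenue_straw - cost_fert - cost_pest - cost_seed -
    cost_fuel - cost_contract - herbicide_addon

  en <- bundle$energy_factors
  ef <- bundle$emission_factors
  sprays <- sum(pesticide_program(bundle, crop)$sprays)
  energy_out <- (grain_t * ci$grain_energy_gj_t + straw_t * ci$straw_energy_gj_t) * 1000
  energy_fert <- applied_n * en$manuf_mj_kg$N + ci$p_rate_kg_ha * en$manuf_mj_kg$P +
    ci$k_rate_kg_ha * en$manuf_mj_kg$K
  energy_pest <- sprays * en$pesticide_mj_spray
  energy_seed <- ci$seed_energy_mj_ha
  energy_fuel <- fuel_l * en$fuel_mj_l
  emb <- vapply(seq_len(nrow(ops)), function(i) {
    imp <- machinery_hourly_embedded(machine_row(bundle, ops$implement[i]), en, ef)
    pw <- if (ops$power[i] != ops$implement[i])
      machinery_hourly_embedded(machine_row(bundle, ops$power[i]), en, ef)
    else c(energy_mj_h = 0, emissions_kgco2e_h = 0)
    ops$hours[i] * (imp + pw)
  }, numeric(2))
  energy_mach <- sum(emb["energy_mj_h", ])
  ghg_mach <- sum(emb["emissions_kgco2e_h", ])
  ne <- energy_out - energy_fert - energy_pest - energy_seed - energy_fuel -
    energy_mach

  ghg_n2o <- soil_n2o_co2e(applied_n, ef)
  ghg_fert <- applied_n * ef$manuf_kgco2e_kg$N +
    ci$p_rate_kg_ha * ef$manuf_kgco2e_kg$P +
    ci$k_rate_kg_ha * ef$manuf_kgco2e_kg$K
  ghg_pest <- sprays * ef$pesticide_kgco2e_spray
  ghg_fuel <- fuel_l * ef$fuel_kgco2e_l
  ghg <- ghg_n2o + ghg_fert + ghg_pest + ghg_fuel + ghg_mach

  data.frame(
    activity = sprintf("%s:%s:N%d", crop, straw, round(n_level * 100)),
    crop = crop, species = ci$species, straw = straw, n_level = n_level,
    tillage = tillage, year = year,
    grain_t = grain_t, straw_t = straw_t, output_t = grain_t + straw_t,
    kcal = grain_t * 1000 * ci$calorie_kcal_kg,
    revenue_grain = revenue_grain, revenue_straw = revenue_straw,
    cost_fert = cost_fert, cost_pest = cost_pest, cost_seed = cost_seed,
    cost_fuel = cost_fuel, cost_contract = cost_contract,
    cost_herbicide_addon = herbicide_addon,
    gm = gm,
    energy_out = energy_out, energy_fert = energy_fert,
    energy_pest = energy_pest, energy_seed = energy_seed,
    energy_fuel = energy_fuel, energy_mach = energy_mach, ne = ne,
    ghg_n2o = ghg_n2o, ghg_fert = ghg_fert, ghg_pest = ghg_pest,
    ghg_fuel = ghg_fuel, ghg_mach = ghg_mach, ghg = ghg,
    fuel_l = fuel_l, drying_fuel_l = drying_l,
    stringsAsFactors = FALSE)
}

#' Coefficient table for every activity under a tillage system
#'
#' Enumerates the activity set (crop variant x straw fate x nitrogen
#' level) and binds their [activity_coefficients()] rows. This table is
#' the audit trail for all farm-level arithmetic: every optimised metric
#' is areas times these columns.
#'
#' @inheritParams activity_coefficients
#' @param crops Optional crop id subset.
#' @return Data frame, one row per activity.
#' @export
activity_table <- function(bundle, tillage, year = "2011",
                           yield_multiplier = 1, herbicide_addon = 0,
                           crops = NULL) {
  g <- activity_grid(bundle)
  if (!is.null(crops)) g <- g[g$crop %in% crops, ]
  do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    activity_coefficients(bundle, g$crop[i], g$straw[i], g$n_level[i],
                          tillage, year, yield_multiplier, herbicide_addon)))
}

#' Write an activity coefficient table to CSV
#'
#' @param tab Result of [activity_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coefficients_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# per-ha in-season resource hours of a crop as a named vector over
# constrained (class, period) slots; establishment hours live on rotation
# flows because their period depends on the predecessor
crop_inseason_hours <- function(bundle, crop, straw) {
  ops <- inseason_ops(bundle, crop, straw)
  ops <- ops[!ops$contract, , drop = FALSE]
  key <- paste(ops$class, ops$period, sep = ".")
  tapply(ops$hours, key, sum)
}
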