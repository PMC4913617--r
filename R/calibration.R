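# Synthetic calibration: the shipped default parameter bundle (published
# table values plus documented placeholders for the inherited calibration
# that is not published) and a seeded random-calibration generator for
# property tests.

#' The shipped default calibration
#'
#' Loads the calibration distributed with the package: every published
#' value (tillage systems, pass matrix and work-rates, machinery weights
#' and steel factors, pesticide programmes, crop and contractor prices,
#' emission factors, farm area, interest rate, depreciation anchors)
#' combined with placeholder values - tagged in the provenance sidecar -
#' for the parameters the model inherits from its predecessor calibration
#' (yields, fuel-use rates, input manufacture factors, energy and calorie
#' contents, labour availability, machinery prices). Placeholders were
#' chosen once so that the conventional-tillage profit-maximising farm
#' selects a three-way wheat/winter-barley/oilseed-rape mix and the
#' qualitative tillage-system orderings of the model's headline outputs
#' hold.
#'
#' @return A validated `farm_bundle`.
#' @export
paperlike_calibration <- function() {
  load_calibration(system.file("extdata", "calibration", package = "cropmix",
                               mustWork = TRUE))
}

#' Seeded random calibration for property testing
#'
#' Perturbs the shipped calibration with uniform multiplicative noise:
#' yields and crop prices +/-10%, work-rates +/-15%, tractor fuel rates
#' +/-10%, period hours +/-20%. Prices and physical coefficients are
#' perturbed independently, so a price draw never changes hours, fuel, NE
#' or GHG. The RNG state is restored on exit; the same seed returns a
#' bit-identical bundle.
#'
#' @param seed Integer seed.
#' @return A validated `farm_bundle`.
#' @export
random_calibration <- function(seed) {
  b <- paperlike_calibration()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  u <- function(n, lo, hi) stats::runif(n, lo, hi)
  nc <- nrow(b$crops)
  b$crops$grain_yield_t_ha <- b$crops$grain_yield_t_ha * u(nc, 0.9, 1.1)
  b$crops$straw_yield_t_ha <- b$crops$straw_yield_t_ha * u(nc, 0.9, 1.1)
  np <- nrow(b$crop_prices)
  for (col in c("grain_2011", "grain_2014", "straw_2011", "straw_2014"))
    b$crop_prices[[col]] <- b$crop_prices[[col]] * u(np, 0.9, 1.1)
  no <- nrow(b$operations)
  b$operations$work_rate_min_ha <- b$operations$work_rate_min_ha * u(no, 0.85, 1.15)
  nm <- nrow(b$machines)
  b$machines$fuel_l_h <- b$machines$fuel_l_h * u(nm, 0.9, 1.1)
  npd <- nrow(b$resources$periods)
  b$resources$periods$unit_hours <- b$resources$periods$unit_hours * u(npd, 0.8, 1.2)
  validate_bundle(b)
  b
}

#' Canonical parameter registry of a calibration bundle
#'
#' Enumerates the parameter names of the bundle at the granularity used by
#' the provenance sidecar; every name must carry exactly one provenance
#' tag (`paper` for published values, `placeholder` for inherited
#' calibration emulation).
#'
#' @param bundle A `farm_bundle` (unused fields reserved).
#' @return Character vector of parameter names.
#' @export
bundle_parameters <- function(bundle) {
  c("crops.set",
    paste0("crops.", c("grain_yield_t_ha", "straw_yield_t_ha",
                       "grain_energy_gj_t", "straw_energy_gj_t",
                       "calorie_kcal_kg", "n_rate_kg_ha", "p_rate_kg_ha",
                       "k_rate_kg_ha", "seed_cost", "seed_energy_mj_ha",
                       "drying_fuel_l_t", "fert_passes")),
    "pesticides.programs",
    paste0("machines.weight_kg.",
           c("onepass_cultivator", "medium_disc", "springtine_harrow", "other")),
    paste0("machines.", c("lifespan_h", "price_gbp", "fuel_l_h",
                          "spares_rate", "insurance_rate", "high_use_h")),
    "depreciation.anchors.tractor", "depreciation.anchors.other",
    "operations.work_rate.tillage", "operations.work_rate.other",
    "passes.matrix", "crop_prices", "contractor_fees",
    paste0("emission_factors.", c("n2o_ef", "n2o_background_kg_n_ha",
                                  "gwp_n2o", "n2o_mass_ratio",
                                  "steel_kgco2e_kg", "fuel_kgco2e_l",
                                  "manuf_kgco2e_kg", "pesticide_kgco2e_spray")),
    paste0("energy_factors.", c("steel_mj_kg", "fuel_mj_l", "manuf_mj_kg",
                                "pesticide_mj_spray")),
    paste0("farm.", c("area_ha", "interest_rate", "labour_units",
                      "machine_units")),
    "periods", "n_response",
    paste0("prices.", c("fert.N", "fert.P", "fert.K", "fuel",
                        "wage_2011", "wage_2014", "contractor_overhead",
                        "labour_surcharge")),
    "rotation.transitions", "tillage_systems")
}
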