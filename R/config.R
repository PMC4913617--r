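# Canonical id sets used throughout the model
.crop_ids <- c("WW1", "WW2", "WWc", "WB", "SB", "WOSR", "WFB")
.tillage_ids <- c("CT", "RP", "DRT", "SRT1", "SRT2", "ZT")
.machine_classes <- c("tractor_small", "tractor_medium", "tractor_large",
                      "combine", "swather", "baler", "implement")
.constrained_classes <- c("tractor_small", "tractor_medium", "tractor_large",
                          "combine")

#' Load a farm calibration bundle from a configuration directory
#'
#' Reads the master YAML file and the table-shaped CSV side files
#' (crops, pesticide programmes, machines, depreciation anchors, field
#' operations, tillage pass matrix, crop prices, contractor fees,
#' provenance) and returns a validated parameter bundle.
#'
#' The configuration dialect is one `master.yaml` holding scalar and
#' nested parameters (farm resources, emission and energy factors,
#' fertiliser/fuel/wage prices, nitrogen response, rotation transitions,
#' tillage system list) plus one CSV per printed-table-shaped input.
#'
#' @param path Directory containing `master.yaml` and the CSV side tables.
#' @return A validated object of class `farm_bundle`.
#' @seealso [write_calibration()], [paperlike_calibration()]
#' @export
load_calibration <- function(path) {
  if (!dir.exists(path))
    stop("calibration directory not found: ", path)
  master_file <- file.path(path, "master.yaml")
  if (!file.exists(master_file))
    stop("validation error: missing section 'master.yaml' in ", path)
  master <- yaml::read_yaml(master_file)

  read_tbl <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f))
      stop("validation error: missing section '", name, "'")
    utils::read.csv(f, stringsAsFactors = FALSE)
  }

  bundle <- structure(list(
    crops           = read_tbl("crops"),
    pesticides      = read_tbl("pesticides"),
    machines        = read_tbl("machines"),
    dep_anchors     = read_tbl("depreciation"),
    operations      = read_tbl("operations"),
    passes          = read_tbl("passes"),
    crop_prices     = read_tbl("crop_prices"),
    contractor_fees = read_tbl("contractor_fees"),
    provenance      = read_tbl("provenance"),
    tillage         = do.call(rbind, lapply(master$tillage_systems, as.data.frame)),
    rotation        = do.call(rbind, lapply(master$rotation, as.data.frame)),
    n_response      = do.call(rbind, lapply(master$n_response, as.data.frame)),
    emission_factors = master$emission_factors,
    energy_factors   = master$energy_factors,
    resources = list(
      area_ha       = master$farm$area_ha,
      interest_rate = master$farm$interest_rate,
      labour_units  = master$farm$labour_units,
      machine_units = unlist(master$farm$machine_units),
      periods       = do.call(rbind, lapply(master$periods, as.data.frame))
    ),
    prices = master$prices
  ), class = "farm_bundle")

  validate_bundle(bundle)
  bundle
}

#' Write a farm calibration bundle back to its configuration dialect
#'
#' Inverse of [load_calibration()]: emits `master.yaml` plus the CSV side
#' tables into `path`. Write-then-load round-trips are lossless (floats
#' are serialised at 12 significant digits).
#'
#' @param bundle A `farm_bundle`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(bundle, path) {
  stopifnot(inherits(bundle, "farm_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(path, paste0(name, ".csv")), row.names = FALSE)
  wr(bundle$crops, "crops")
  wr(bundle$pesticides, "pesticides")
  wr(bundle$machines, "machines")
  wr(bundle$dep_anchors, "depreciation")
  wr(bundle$operations, "operations")
  wr(bundle$passes, "passes")
  wr(bundle$crop_prices, "crop_prices")
  wr(bundle$contractor_fees, "contractor_fees")
  wr(bundle$provenance, "provenance")

  master <- list(
    farm = list(
      area_ha       = bundle$resources$area_ha,
      interest_rate = bundle$resources$interest_rate,
      labour_units  = bundle$resources$labour_units,
      machine_units = as.list(bundle$resources$machine_units)
    ),
    periods = lapply(seq_len(nrow(bundle$resources$periods)), function(i)
      as.list(bundle$resources$periods[i, ])),
    emission_factors = bundle$emission_factors,
    energy_factors   = bundle$energy_factors,
    n_response = lapply(seq_len(nrow(bundle$n_response)), function(i)
      as.list(bundle$n_response[i, ])),
    prices = bundle$prices,
    tillage_systems = lapply(seq_len(nrow(bundle$tillage)), function(i)
      as.list(bundle$tillage[i, ])),
    rotation = lapply(seq_len(nrow(bundle$rotation)), function(i)
      as.list(bundle$rotation[i, ]))
  )
  writeLines(yaml::as.yaml(master, precision = 12),
             file.path(path, "master.yaml"))
  invisible(path)
}

#' Validate a farm parameter bundle
#'
#' Checks structural completeness, value invariants (non-negative yields,
#' passes and prices, positive work-rates and weights, strictly increasing
#' depreciation anchors) and that every cross-reference (crop ids in the
#' pass matrix, machine ids in operations and fee tables, rotation crop
#' ids) resolves. Errors name the offending field.
#'
#' @param bundle A `farm_bundle`.
#' @return The bundle, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  fail <- function(...) stop("validation error: ", ..., call. = FALSE)
  cr <- bundle$crops
  if (!setequal(cr$id, .crop_ids)) fail("crops.id must be exactly ", paste(.crop_ids, collapse = ", "))
  if (any(cr$grain_yield_t_ha < 0) || any(cr$straw_yield_t_ha < 0))
    fail("crops: yields must be >= 0")
  if (!setequal(cr$id[cr$category == "break"], c("WOSR", "WFB")))
    fail("crops.category: break crops must be WOSR and WFB only")
  if (any(!cr$sowing %in% c("autumn", "spring"))) fail("crops.sowing")
  if (any(cr$n_rate_kg_ha < 0 | cr$p_rate_kg_ha < 0 | cr$k_rate_kg_ha < 0))
    fail("crops: fertiliser rates must be >= 0")
  if (any(cr$seed_cost_2011 < 0 | cr$seed_cost_2014 < 0)) fail("crops.seed_cost")

  pp <- bundle$pesticides
  if (any(pp$cost_2011 < 0 | pp$cost_2014 < 0)) fail("pesticides.cost must be >= 0")
  if (any(pp$sprays < 1)) fail("pesticides.sprays must be >= 1")
  if (!all(pp$crop %in% cr$species)) fail("pesticides.crop: dangling crop id")

  mm <- bundle$machines
  if (any(mm$weight_kg <= 0)) fail("machines.weight_kg must be > 0")
  if (any(mm$lifespan_h <= 0)) fail("machines.lifespan_h must be > 0")
  if (any(!mm$class %in% .machine_classes)) fail("machines.class")
  if (any(mm$price_gbp < 0)) fail("machines.price_gbp")

  da <- bundle$dep_anchors
  if (!all(da$machine %in% mm$id)) fail("depreciation.machine: dangling machine id")
  for (m in unique(da$machine)) {
    x <- da[da$machine == m, ]
    x <- x[order(x$hours), ]
    if (nrow(x) < 2 || any(diff(x$hours) <= 0) || any(diff(x$rate) <= 0))
      fail("depreciation anchors for '", m,
           "' must be strictly increasing in hours and rates")
  }

  op <- bundle$operations
  if (any(op$work_rate_min_ha <= 0)) fail("operations.work_rate_min_ha must be > 0")
  if (!all(op$implement %in% mm$id)) fail("operations.implement: dangling machine id")
  if (!all(op$power %in% c("self", mm$id))) fail("operations.power: dangling machine id")

  pa <- bundle$passes
  sp_cols <- c("WW", "WOSR", "WB", "SB", "WFB")
  if (!all(sp_cols %in% names(pa))) fail("passes: missing crop column")
  if (any(as.matrix(pa[, sp_cols]) < 0)) fail("passes must be >= 0")
  if (!all(pa$op %in% op$id)) fail("passes.op: dangling operation id")
  if (!all(pa$tillage %in% bundle$tillage$id)) fail("passes.tillage: dangling tillage id")
  if (!setequal(bundle$tillage$id, .tillage_ids)) fail("tillage_systems ids")

  cp <- bundle$crop_prices
  if (any(cp$grain_2011 < 0 | cp$grain_2014 < 0, na.rm = TRUE)) fail("crop_prices.grain")
  if (any(cp$straw_2011 < 0 | cp$straw_2014 < 0, na.rm = TRUE)) fail("crop_prices.straw")
  if (!all(cr$species %in% cp$crop)) fail("crop_prices: missing crop")

  cf <- bundle$contractor_fees
  if (!all(cf$machine %in% mm$id)) fail("contractor_fees.machine: dangling machine id")
  if (any(cf$fee_2011 < 0 | cf$fee_2014 < 0)) fail("contractor_fees: fees must be >= 0")

  ro <- bundle$rotation
  if (!all(ro$from %in% cr$id) || !all(ro$to %in% cr$id))
    fail("rotation: dangling crop id")

  ef <- bundle$emission_factors
  if (any(unlist(ef) < 0)) fail("emission_factors must be >= 0")
  en <- bundle$energy_factors
  if (any(unlist(en) <= 0)) fail("energy_factors must be > 0")

  rs <- bundle$resources
  if (rs$area_ha <= 0) fail("farm.area_ha must be > 0")
  if (any(rs$periods$unit_hours < 0)) fail("periods.unit_hours must be >= 0")
  if (!all(names(rs$machine_units) %in% .machine_classes)) fail("farm.machine_units")

  for (yr in names(bundle$prices)) {
    p <- bundle$prices[[yr]]
    if (any(unlist(p$fert_gbp_kg) < 0) || p$fuel_gbp_l < 0 || p$wage_gbp_h < 0)
      fail("prices.", yr, ": prices must be >= 0")
  }

  nr <- bundle$n_response
  if (!all(c(0.5, 0.75, 1.0) %in% nr$level)) fail("n_response levels")

  invisible(bundle)
}

#' Percent change between an old and a new price
#'
#' Computes `100 * (new - old) / old`, reported to one decimal place, the
#' convention used by the price-difference columns of the shipped price
#' tables.
#'
#' @param old Old value (must be non-zero).
#' @param new New value.
#' @return Percent change, rounded to one decimal.
#' @examples
#' percent_change(36.01, 44.04)   # +22.3
#' percent_change(374.08, 290.49) # -22.3
#' @export
percent_change <- function(old, new) {
  if (any(old == 0)) stop("percent change undefined for old value 0")
  round(100 * (new - old) / old, 1)
}

#' @export
print.farm_bundle <- function(x, ...) {
  cat("<farm_bundle>\n")
  cat("  crops:          ", nrow(x$crops), " variants (",
      paste(x$crops$id, collapse = ", "), ")\n", sep = "")
  cat("  tillage systems:", nrow(x$tillage), "\n")
  cat("  machines:       ", nrow(x$machines), "\n")
  cat("  farm area:      ", x$resources$area_ha, "ha\n")
  cat("  price years:    ", paste(names(x$prices), collapse = ", "), "\n")
  invisible(x)
}

# fee per hour for a machine id and price year
contractor_fee <- function(bundle, machine, year) {
  cf <- bundle$contractor_fees
  i <- match(machine, cf$machine)
  if (is.na(i)) stop("no contractor fee for machine '", machine, "'")
  cf[[paste0("fee_", year)]][i]
}
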