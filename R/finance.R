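# Whole-farm finance: machinery complement, usage-dependent depreciation,
# spares & repairs, insurance, interest and labour -> net margin.

#' Usage-dependent straight-line depreciation rate
#'
#' Annual depreciation is a fraction of purchase price that grows with
#' annual use; the rate is piecewise-linear interpolated between the
#' machine's anchor points and clamped at the end anchors (e.g. tractors:
#' 15% at 500 h/yr rising to 27% at 1500 h/yr).
#'
#' @param bundle A `farm_bundle`.
#' @param machine Machine id.
#' @param annual_hours Hours of use per year (>= 0).
#' @return Depreciation rate, fraction of purchase price per year.
#' @export
depreciation_rate <- function(bundle, machine, annual_hours) {
  if (any(annual_hours < 0)) stop("annual hours must be >= 0")
  a <- bundle$dep_anchors[bundle$dep_anchors$machine == machine, ]
  if (nrow(a) == 0) stop("empty depreciation schedule for '", machine, "'")
  stats::approx(a$hours, a$rate, xout = annual_hours, rule = 2)$y
}

#' Size the machinery complement implied by a farm solution
#'
#' The farm owns exactly the machines whose operations appear with
#' positive own-farm hours in the solution: the tillage/drilling
#' implements of the system actually used, the in-season implements
#' (sprayer, spreader), the combine, and the tractor classes that power
#' them. Swather and baler work is always contracted and never owned.
#' Tractor classes are owned in the fleet unit counts of the calibration,
#' with class hours split evenly across units.
#'
#' @param solution A `farm_solution`.
#' @param bundle A `farm_bundle`.
#' @return Object of class `machinery_complement`: data frame with one row
#'   per owned machine (units, annual hours per unit, depreciation, spares
#'   & repairs, insurance, interest and total annual cost in GBP).
#' @export
size_complement <- function(solution, bundle) {
  oh <- solution$op_hours
  rows <- list()
  add <- function(id, units, hours_per_unit) {
    if (hours_per_unit <= 1e-9) return()
    m <- machine_row(bundle, id)
    dep <- m$price_gbp * depreciation_rate(bundle, id, hours_per_unit)
    spares <- m$price_gbp * m$spares_rate
    ins <- m$price_gbp * m$insurance_rate
    int <- bundle$resources$interest_rate * m$price_gbp / 2
    rows[[length(rows) + 1]] <<- data.frame(
      machine = id, units = units, annual_hours = hours_per_unit,
      depreciation = units * dep, spares_repairs = units * spares,
      insurance = units * ins, interest = units * int,
      total = units * (dep + spares + ins + int))
  }
  if (nrow(oh)) {
    imp <- stats::aggregate(own_hours ~ implement, oh, sum)
    imp <- imp[!imp$implement %in% c("swather", "baler"), , drop = FALSE]
    for (i in seq_len(nrow(imp))) {
      cls <- machine_row(bundle, imp$implement[i])$class
      if (cls == "implement") add(imp$implement[i], 1, imp$own_hours[i])
    }
    pw <- oh[oh$power != oh$implement, , drop = FALSE]
    if (nrow(pw)) {
      tr <- stats::aggregate(own_hours ~ power, pw, sum)
      for (i in seq_len(nrow(tr))) {
        units <- unname(bundle$resources$machine_units[
          machine_row(bundle, tr$power[i])$class])
        if (is.na(units) || units < 1) units <- 1
        add(tr$power[i], units, tr$own_hours[i] / units)
      }
    }
    self <- oh[oh$power == oh$implement &
                 !oh$implement %in% c("swather", "baler"), , drop = FALSE]
    if (nrow(self)) {
      sf <- stats::aggregate(own_hours ~ implement, self, sum)
      for (i in seq_len(nrow(sf))) add(sf$implement[i], 1, sf$own_hours[i])
    }
  }
  comp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(machine = character(0), units = numeric(0),
               annual_hours = numeric(0), depreciation = numeric(0),
               spares_repairs = numeric(0), insurance = numeric(0),
               interest = numeric(0), total = numeric(0))
  structure(comp, class = c("machinery_complement", "data.frame"))
}

#' Whole-farm net margin report
#'
#' Net margin is gross margin less machinery ownership costs
#' (usage-dependent depreciation, spares & repairs, insurance, interest on
#' half the purchase price) and own labour (own machine hours times the
#' wage). Fuel and contractor fees are already inside the gross margin.
#'
#' @param solution A `farm_solution`.
#' @param complement A `machinery_complement` from [size_complement()].
#' @param bundle A `farm_bundle`.
#' @param extra_machinery_cost Additional whole-farm machinery/fuel/labour
#'   cost in GBP (e.g. the extra spraying pass of weed-control scenarios).
#' @return Object of class `net_margin_report`.
#' @export
net_margin <- function(solution, complement, bundle,
                       extra_machinery_cost = 0) {
  pr <- bundle$prices[[solution$year]]
  area <- solution$area_ha
  labour <- solution$own_hours_total * pr$wage_gbp_h
  machinery <- sum(complement$total) + extra_machinery_cost
  nm <- solution$gm - machinery - labour
  structure(list(
    tillage = solution$tillage, year = solution$year,
    gm = solution$gm, gm_ha = solution$gm / area,
    fuel_l = solution$fuel_l,
    fuel_cost = solution$fuel_l * pr$fuel_gbp_l,
    contractor_fees = solution$contractor_fees,
    machinery = machinery, machinery_ha = machinery / area,
    labour_h = solution$own_hours_total,
    labour = labour, labour_ha = labour / area,
    extra_machinery_cost = extra_machinery_cost,
    nm = nm, nm_ha = nm / area
  ), class = "net_margin_report")
}

#' @export
print.net_margin_report <- function(x, ...) {
  cat("<net_margin_report> ", x$tillage, " / ", x$year, "\n", sep = "")
  cat(sprintf("  GM          %10.0f GBP/farm (%.0f /ha)\n", x$gm, x$gm_ha))
  cat(sprintf("  fuel        %10.0f L (%.0f GBP)\n", x$fuel_l, x$fuel_cost))
  cat(sprintf("  contractors %10.0f GBP\n", x$contractor_fees))
  cat(sprintf("  machinery   %10.0f GBP (%.0f /ha)\n", x$machinery, x$machinery_ha))
  cat(sprintf("  labour      %10.0f GBP (%.0f /ha)\n", x$labour, x$labour_ha))
  cat(sprintf("  NM          %10.0f GBP/farm (%.0f /ha)\n", x$nm, x$nm_ha))
  invisible(x)
}

#' Write a net-margin report as a CSV table
#'
#' One row per line of the report (GM per ha, fuel, contractors' fees,
#' machinery, labour, net margin per farm and per ha).
#'
#' @param report A `net_margin_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_net_margin_csv <- function(report, path) {
  df <- data.frame(
    item = c("GM (GBP/ha)", "Fuel use (L/farm)", "Fuel costs (GBP/farm)",
             "Contractors' fees (GBP/farm)", "Machinery costs (GBP/farm)",
             "Machinery costs (GBP/ha)", "Labour costs (GBP/farm)",
             "Labour costs (GBP/ha)", "Net margin (GBP/farm)",
             "Net margin (GBP/ha)"),
    value = round(c(report$gm_ha, report$fuel_l, report$fuel_cost,
                    report$contractor_fees, report$machinery,
                    report$machinery_ha, report$labour, report$labour_ha,
                    report$nm, report$nm_ha), 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a contractor fee from machinery costs (2014 method)
#'
#' The 2014 fees are built from machine costs at a high annual usage rate:
#' hourly ownership and running cost (usage-dependent depreciation, spares
#' & repairs, insurance and interest, divided by high-use hours, plus
#' fuel) marked up by a 25% overhead, plus the labour wage with a 35%
#' surcharge (10.19 x 1.35 = 13.76 GBP/h). 2011 fees are read directly
#' from the fee table and do not use this construction.
#'
#' @param bundle A `farm_bundle`.
#' @param machine Machine id.
#' @return Fee in GBP per hour.
#' @export
contractor_fee_2014 <- function(bundle, machine) {
  m <- machine_row(bundle, machine)
  pr <- bundle$prices[["2014"]]
  dep <- m$price_gbp * depreciation_rate(bundle, machine, m$high_use_h)
  own <- dep + m$price_gbp * (m$spares_rate + m$insurance_rate) +
    bundle$resources$interest_rate * m$price_gbp / 2
  fuel <- if (is.na(m$fuel_l_h)) 0 else m$fuel_l_h * pr$fuel_gbp_l
  hourly <- own / m$high_use_h + fuel
  hourly * (1 + pr$contractor_overhead) +
    pr$wage_gbp_h * (1 + pr$labour_surcharge)
}
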