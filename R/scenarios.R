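# Scenario engine: tillage comparisons, yield-penalty thresholds with
# land/calorie compensation, weed-control costs, spring-barley selection
# sweep and the full scenario matrix.

# farm-level metric for a tillage system at uniform yield penalty p
.threshold_metric <- function(bundle, tillage, metric, p, year, greening,
                              ct_baseline_solution = NULL,
                              tillage_options = list()) {
  obj <- if (metric == "NE") "max_NE" else "max_GM"
  opts <- utils::modifyList(list(greening = greening), tillage_options)
  opts$yield_multiplier <- 1 - p
  sol <- optimize_farm(bundle, tillage, year, obj, options = opts)
  val <- switch(metric,
    GM = sol$gm,
    NE = sol$ne,
    GHG_per_t = sol$ghg / sol$output_t,
    GHG_total_constant_production = {
      comp <- land_compensation(sol, ct_baseline_solution, bundle)
      comp$total_ghg_constant_production
    })
  list(value = val, solution = sol)
}

#' Breakeven yield-penalty threshold for a tillage system
#'
#' Finds the uniform yield penalty `p*` at which the chosen farm-level
#' metric of the (re-optimised) tillage system equals the
#' conventional-tillage baseline at zero penalty, by bisection over the
#' penalty with a full LP re-optimisation at every step. The optimised
#' metric is nonincreasing in the penalty for GM and NE (and the
#' GHG-per-tonne and constant-production-GHG metrics are nondecreasing),
#' so the crossing, when it exists in [0, 1], is unique.
#'
#' @param bundle A `farm_bundle`.
#' @param tillage Tillage system id.
#' @param metric `"GM"`, `"NE"`, `"GHG_per_t"` or
#'   `"GHG_total_constant_production"`.
#' @param year Price year.
#' @param tol Absolute tolerance on the metric at the threshold; default
#'   `1e-6 * |baseline|`.
#' @param greening Apply Greening constraints.
#' @param tillage_options Extra [build_program()] options applied to the
#'   penalised tillage solves (not to the conventional-tillage baseline),
#'   e.g. a crop subset that pins the mix.
#' @return Object of class `threshold_result`: `p_star` (NA if no crossing
#'   in [0, 1]), `baseline_value`, `value_at_threshold`, the re-optimised
#'   solution at `p_star`, and `status`.
#' @export
yield_threshold <- function(bundle, tillage,
                            metric = c("GM", "NE", "GHG_per_t",
                                       "GHG_total_constant_production"),
                            year = "2011", tol = NULL, greening = FALSE,
                            tillage_options = list()) {
  metric <- match.arg(metric)
  ct0 <- optimize_farm(bundle, "CT", year, "max_GM",
                       options = list(greening = greening))
  baseline <- switch(metric,
    GM = ct0$gm,
    NE = optimize_farm(bundle, "CT", year, "max_NE",
                       options = list(greening = greening))$ne,
    GHG_per_t = ct0$ghg / ct0$output_t,
    GHG_total_constant_production = ct0$ghg)
  if (is.null(tol)) tol <- 1e-6 * abs(baseline)

  # a zero-output farm (total yield penalty) has undefined per-output
  # metrics; treat it as +Inf so the bracket sign is still meaningful
  g <- function(p) {
    val <- tryCatch(
      .threshold_metric(bundle, tillage, metric, p, year, greening, ct0,
                        tillage_options)$value,
      error = function(e) Inf)
    val - baseline
  }
  g0 <- g(0); g1 <- g(1)
  res <- list(tillage = tillage, metric = metric, year = year,
              baseline_value = baseline)
  if (abs(g0) <= tol) {
    r <- .threshold_metric(bundle, tillage, metric, 0, year, greening, ct0,
                           tillage_options)
    res <- c(res, list(p_star = 0, value_at_threshold = r$value,
                       solution = r$solution, status = "threshold"))
  } else if (sign(g0) == sign(g1)) {
    res <- c(res, list(p_star = NA_real_, value_at_threshold = NA_real_,
                       solution = NULL, status = "no threshold"))
  } else {
    lo <- 0; hi <- 1
    while (hi - lo > 5e-5) {
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(g0)) lo <- mid else hi <- mid
    }
    p_star <- (lo + hi) / 2
    r <- .threshold_metric(bundle, tillage, metric, p_star, year, greening,
                           ct0, tillage_options)
    res <- c(res, list(p_star = p_star, value_at_threshold = r$value,
                       solution = r$solution, status = "threshold"))
  }
  structure(res, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> ", x$tillage, " / ", x$metric, "\n", sep = "")
  if (is.na(x$p_star)) cat("  no threshold in [0, 1]\n")
  else cat(sprintf("  p* = %.4f (baseline %.4g, value at p* %.4g)\n",
                   x$p_star, x$baseline_value, x$value_at_threshold))
  invisible(x)
}

#' Extra land needed to restore baseline output, and its GHG cost
#'
#' Given a penalised solution and a baseline solution, computes the extra
#' land fraction required for the penalised farm - keeping its own crop
#' mix - to produce the baseline output, in tonnes and in calories, and
#' the total GHG when the extra hectares (calorie basis) emit at the
#' penalised farm's per-hectare rate. With an unchanged crop mix and
#' penalty `p` the extra fraction is exactly `1/(1-p) - 1`; a mix shifted
#' toward lower-yielding crops needs strictly more.
#'
#' @param solution_p Penalised `farm_solution`.
#' @param baseline_solution Baseline `farm_solution`.
#' @param bundle A `farm_bundle`.
#' @return Object of class `compensation_result`.
#' @export
land_compensation <- function(solution_p, baseline_solution, bundle) {
  if (baseline_solution$output_t <= 0) stop("baseline output must be > 0")
  if (solution_p$output_t <= 1e-9 || solution_p$kcal <= 1e-9)
    stop("penalised output is zero; compensation undefined")
  area <- bundle$resources$area_ha
  extra_t <- baseline_solution$output_t / solution_p$output_t - 1
  extra_kcal <- baseline_solution$kcal / solution_p$kcal - 1
  extra_ha <- max(extra_kcal, 0) * area
  structure(list(
    extra_land_frac_t = extra_t,
    extra_land_frac_kcal = extra_kcal,
    extra_ha = extra_ha,
    total_ghg_constant_production = solution_p$ghg +
      extra_ha * solution_p$ghg / area
  ), class = "compensation_result")
}

#' Weed-control (black-grass herbicide) scenario
#'
#' Adds an annualised black-grass herbicide cost to every activity's gross
#' margin (a biennial 85 GBP/ha application averaged to 42.50 GBP/ha/yr in
#' the steady-state single-year model; the extreme variant applies the
#' full 85 GBP/ha/yr), re-optimises, and charges the extra spraying pass
#' (4.81 GBP/ha, machinery + fuel + labour) to the net-margin costs. The
#' `spray_basis` switch controls whether the spraying charge follows the
#' application frequency (`"per_application"`, i.e. halved when the
#' herbicide is biennial) or is charged every year (`"per_year"`).
#'
#' @param bundle A `farm_bundle`.
#' @param tillage Tillage system id.
#' @param year Price year.
#' @param extreme Apply the full 85 GBP/ha/yr instead of 42.50.
#' @param herbicide_cost_ha Cost of one black-grass application, GBP/ha.
#' @param spray_cost_ha Machinery/fuel/labour cost of the extra spraying
#'   pass, GBP/ha.
#' @param spray_basis `"per_application"` or `"per_year"`.
#' @param greening Apply Greening constraints.
#' @return List: `solution`, `complement`, `net_margin`, `addon`.
#' @export
weed_control_scenario <- function(bundle, tillage, year = "2011",
                                  extreme = FALSE, herbicide_cost_ha = 85,
                                  spray_cost_ha = 4.81,
                                  spray_basis = c("per_application", "per_year"),
                                  greening = FALSE) {
  spray_basis <- match.arg(spray_basis)
  addon <- if (extreme) herbicide_cost_ha else herbicide_cost_ha / 2
  sol <- optimize_farm(bundle, tillage, year, "max_GM",
                       options = list(herbicide_addon = addon,
                                      greening = greening))
  comp <- size_complement(sol, bundle)
  spray_frac <- if (extreme || spray_basis == "per_year") 1 else 0.5
  extra <- spray_cost_ha * spray_frac * bundle$resources$area_ha
  nm <- net_margin(sol, comp, bundle, extra_machinery_cost = extra)
  list(solution = sol, complement = comp, net_margin = nm, addon = addon)
}

#' Spring-barley selection sweep
#'
#' Applies a uniform yield penalty to every crop except spring barley,
#' re-optimises for gross margin at each penalty on the grid, and reports
#' the optimised spring-barley area. Spring barley, with its stale-seedbed
#' weed-control value but low yield, enters only once the penalty on the
#' autumn-sown crops is large; the attributes report the entry threshold
#' and the penalty at which its area first exceeds 100 ha.
#'
#' @param bundle A `farm_bundle`.
#' @param tillage Tillage system id.
#' @param year Price year.
#' @param penalties Numeric vector of penalties in [0, 1).
#' @return Data frame (`penalty`, `sb_area_ha`, `gm`) with attributes
#'   `entry_threshold` and `penalty_over_100ha` (NA if never reached).
#' @export
sb_selection_sweep <- function(bundle, tillage = "ZT", year = "2011",
                               penalties = seq(0, 0.30, by = 0.02)) {
  crops <- bundle$crops$id
  rows <- lapply(penalties, function(p) {
    ym <- stats::setNames(rep(1 - p, length(crops)), crops)
    ym["SB"] <- 1
    sol <- optimize_farm(bundle, tillage, year, "max_GM",
                         options = list(yield_multiplier = ym))
    sb <- sum(sol$areas[sol$activities$crop == "SB"])
    data.frame(penalty = p, sb_area_ha = sb, gm = sol$gm)
  })
  out <- do.call(rbind, rows)
  entered <- out$penalty[out$sb_area_ha > 1e-6]
  big <- out$penalty[out$sb_area_ha > 100]
  attr(out, "entry_threshold") <- if (length(entered)) min(entered) else NA_real_
  attr(out, "penalty_over_100ha") <- if (length(big)) min(big) else NA_real_
  out
}

#' Run the full scenario matrix
#'
#' Solves every combination of price year, tillage system, objective and
#' Greening flag; collects the crop mixes and the three metrics; derives
#' net-margin reports for the GM-maximising solutions; and summarises the
#' pairwise deltas against conventional tillage (GM premium in %, fuel
#' reduction in %, NM difference in GBP/ha), rounded to the nearest
#' integer percent and nearest GBP. Failed solves are recorded in the
#' metrics table with their error message, never dropped.
#'
#' @param bundle A `farm_bundle`.
#' @param years Character vector of price years.
#' @param tillages Character vector of tillage system ids.
#' @param objectives Character vector of objectives.
#' @param greening Logical vector of Greening flags to sweep.
#' @return Object of class `scenario_matrix`: list with `metrics`,
#'   `net_margin`, `deltas` data frames and `solutions` (named list).
#' @export
scenario_matrix <- function(bundle, years = "2011",
                            tillages = c("CT", "RP", "DRT", "SRT1", "SRT2", "ZT"),
                            objectives = c("max_GM", "max_NE", "min_GHG"),
                            greening = FALSE) {
  metrics <- NULL; nm_tab <- NULL; solutions <- list()
  for (yr in years) for (g in greening) for (tl in tillages)
    for (ob in objectives) {
      key <- paste(yr, tl, ob, if (g) "greening" else "base", sep = "/")
      sol <- tryCatch(
        optimize_farm(bundle, tl, yr, ob, options = list(greening = g)),
        error = function(e) e)
      if (inherits(sol, "error")) {
        metrics <- rbind(metrics, data.frame(
          year = yr, greening = g, tillage = tl, objective = ob,
          status = conditionMessage(sol), gm = NA, ne = NA, ghg = NA,
          fuel_l = NA, contractor_fees = NA))
        next
      }
      solutions[[key]] <- sol
      metrics <- rbind(metrics, data.frame(
        year = yr, greening = g, tillage = tl, objective = ob,
        status = "optimal", gm = sol$gm, ne = sol$ne, ghg = sol$ghg,
        fuel_l = sol$fuel_l, contractor_fees = sol$contractor_fees))
      if (ob == "max_GM") {
        comp <- size_complement(sol, bundle)
        nm <- net_margin(sol, comp, bundle)
        nm_tab <- rbind(nm_tab, data.frame(
          year = yr, greening = g, tillage = tl,
          gm_ha = nm$gm_ha, fuel_l = nm$fuel_l, fuel_cost = nm$fuel_cost,
          contractor_fees = nm$contractor_fees, machinery = nm$machinery,
          machinery_ha = nm$machinery_ha, labour = nm$labour,
          labour_ha = nm$labour_ha, nm = nm$nm, nm_ha = nm$nm_ha))
      }
    }
  deltas <- NULL
  if (!is.null(metrics)) {
    ok <- metrics[metrics$status == "optimal", ]
    for (yr in unique(ok$year)) for (g in unique(ok$greening))
      for (ob in unique(ok$objective)) {
        sub <- ok[ok$year == yr & ok$greening == g & ok$objective == ob, ]
        ct <- sub[sub$tillage == "CT", ]
        if (nrow(ct) != 1) next
        for (i in seq_len(nrow(sub))) {
          if (sub$tillage[i] == "CT") next
          nmsub <- nm_tab[nm_tab$year == yr & nm_tab$greening == g, ]
          nm_d <- if (ob == "max_GM" && "CT" %in% nmsub$tillage &&
                      sub$tillage[i] %in% nmsub$tillage)
            round(nmsub$nm_ha[nmsub$tillage == sub$tillage[i]] -
                  nmsub$nm_ha[nmsub$tillage == "CT"])
          else NA_real_
          deltas <- rbind(deltas, data.frame(
            year = yr, greening = g, objective = ob,
            tillage = sub$tillage[i],
            gm_premium_pct = round(100 * (sub$gm[i] / ct$gm - 1)),
            fuel_reduction_pct = round(100 * (1 - sub$fuel_l[i] / ct$fuel_l)),
            ghg_reduction_pct = round(100 * (1 - sub$ghg[i] / ct$ghg)),
            nm_diff_gbp_ha = nm_d))
        }
      }
  }
  structure(list(metrics = metrics, net_margin = nm_tab, deltas = deltas,
                 solutions = solutions),
            class = "scenario_matrix")
}

#' Write a scenario matrix to a directory of CSV files
#'
#' @param sm A `scenario_matrix`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario_matrix <- function(sm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sm$metrics))
    utils::write.csv(sm$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(sm$net_margin))
    utils::write.csv(sm$net_margin, file.path(dir, "net_margin.csv"),
                     row.names = FALSE)
  if (!is.null(sm$deltas))
    utils::write.csv(sm$deltas, file.path(dir, "deltas.csv"), row.names = FALSE)
  for (key in names(sm$solutions)) {
    f <- file.path(dir, paste0("mix_", gsub("/", "_", key), ".csv"))
    write_solution(sm$solutions[[key]], csv = f)
  }
  invisible(dir)
}

# md5 of the serialised bundle, for run logs
calibration_hash <- function(bundle) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(bundle, f)
  unname(tools::md5sum(f))
}
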