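# Farm linear programme: choose activity areas to maximise gross margin,
# maximise net energy or minimise GHG emissions subject to land,
# steady-state rotation, work-period resource / contractor and optional
# CAP-Greening constraints.

# period in which the establishment of `to` on land coming out of `from`
# takes place: spring crops are established in spring; oilseed rape must be
# established in the early-autumn window whatever the predecessor; other
# autumn establishment follows the predecessor's harvest timing
period_for_flow <- function(bundle, from, to) {
  ct <- bundle$crops[match(to, bundle$crops$id), ]
  cf <- bundle$crops[match(from, bundle$crops$id), ]
  if (ct$sowing == "spring") return("spring")
  if (ct$species == "WOSR") return("earlyautumn")
  if (cf$harvest == "early") "earlyautumn" else "autumn"
}

#' Build the farm linear programme
#'
#' Decision variables are activity areas (ha), steady-state rotation flows
#' (ha from predecessor crop to successor crop) and contractor hours per
#' (machine class, work period). Constraints: land balance (areas sum to
#' the farm area); rotation flow conservation (each crop's area equals
#' both its inflow and its outflow); per-period machine-class and labour
#' balances where contractor hours (bounded by the hours actually
#' required) relax capacity at the contractor fee; and, optionally, the
#' Greening pairwise species caps (see [apply_greening()]).
#'
#' @param bundle A `farm_bundle`.
#' @param tillage Tillage system id.
#' @param year Price year.
#' @param objective `"max_GM"`, `"max_NE"` or `"min_GHG"`.
#' @param options List: `greening` (logical), `yield_multiplier` (scalar or
#'   named by crop), `herbicide_addon` (GBP/ha/yr), `crops` (optional crop
#'   id subset for reduced instances), `rotation` (set `FALSE` to drop
#'   rotation constraints), `unconstrained_resources` (set `TRUE` to lift
#'   all capacity limits).
#' @return An object of class `farm_program`.
#' @export
build_program <- function(bundle, tillage, year = "2011",
                          objective = c("max_GM", "max_NE", "min_GHG"),
                          options = list()) {
  objective <- match.arg(objective)
  opt <- utils::modifyList(list(greening = FALSE, yield_multiplier = 1,
                         herbicide_addon = 0, crops = NULL,
                         rotation = TRUE, unconstrained_resources = FALSE),
                    options)

  acts <- activity_table(bundle, tillage, year,
                         yield_multiplier = opt$yield_multiplier,
                         herbicide_addon = opt$herbicide_addon,
                         crops = opt$crops)
  na <- nrow(acts)
  if (na == 0) stop("no activities to optimise")

  flows <- bundle$rotation
  if (!is.null(opt$crops))
    flows <- flows[flows$from %in% opt$crops & flows$to %in% opt$crops, ]
  if (!opt$rotation) flows <- flows[0, ]
  nf <- nrow(flows)
  if (nf)
    flows$period <- vapply(seq_len(nf), function(i)
      period_for_flow(bundle, flows$from[i], flows$to[i]), character(1))

  periods <- bundle$resources$periods$id
  unit_h <- stats::setNames(bundle$resources$periods$unit_hours, periods)
  slots <- expand.grid(class = .constrained_classes, period = periods,
                       stringsAsFactors = FALSE)
  slots$key <- paste(slots$class, slots$period, sep = ".")
  ns <- nrow(slots)
  units <- bundle$resources$machine_units
  slots$cap <- unname(units[slots$class]) * unit_h[slots$period]
  labour <- bundle$resources$labour_units * unit_h
  if (opt$unconstrained_resources) {
    slots$cap <- 1e9
    labour[] <- 1e9
  }
  fees <- vapply(slots$class, function(cl)
    contractor_fee(bundle, cl, year), numeric(1))
  slots$fee <- fees

  # per-activity in-season hours over slots
  act_hours <- matrix(0, na, ns, dimnames = list(acts$activity, slots$key))
  for (i in seq_len(na)) {
    h <- crop_inseason_hours(bundle, acts$crop[i], acts$straw[i])
    act_hours[i, names(h)] <- h
  }
  # per-flow establishment hours over slots
  flow_hours <- matrix(0, nf, ns, dimnames = list(NULL, slots$key))
  if (nf) for (i in seq_len(nf)) {
    e <- operation_hours_and_fuel(bundle, tillage, flows$to[i])$hours_by_class
    if (length(e))
      flow_hours[i, paste(names(e), flows$period[i], sep = ".")] <- e
  }

  nv <- na + nf + ns
  ia <- seq_len(na); iflow <- na + seq_len(nf); ih <- na + nf + seq_len(ns)

  # equalities: land balance + rotation flow conservation
  crops_in <- unique(acts$crop)
  A3 <- matrix(0, 1 + 2 * length(crops_in) * (nf > 0), nv)
  A3[1, ia] <- 1
  b3 <- bundle$resources$area_ha
  if (nf) {
    r <- 1
    for (cc in crops_in) {
      r <- r + 1
      A3[r, ia[acts$crop == cc]] <- 1
      A3[r, iflow[flows$to == cc]] <- -1
      r <- r + 1
      A3[r, ia[acts$crop == cc]] <- 1
      A3[r, iflow[flows$from == cc]] <- -1
    }
    b3 <- c(b3, rep(0, 2 * length(crops_in)))
    # the flow-conservation system is rank-deficient by construction
    # (total inflow equals total outflow); keep a full-rank row subset
    q <- qr(t(A3))
    keep <- sort(q$pivot[seq_len(q$rank)])
    A3 <- A3[keep, , drop = FALSE]
    b3 <- b3[keep]
  }

  # inequalities: capacity, labour, hire bounds
  A1 <- NULL; b1 <- NULL; groups <- character(0)
  for (r in seq_len(ns)) {
    row <- numeric(nv)
    row[ia] <- act_hours[, r]
    if (nf) row[iflow] <- flow_hours[, r]
    row[ih[r]] <- -1
    A1 <- rbind(A1, row); b1 <- c(b1, slots$cap[r])
    groups <- c(groups, paste0("capacity:", slots$key[r]))
  }
  for (p in periods) {
    sel <- which(slots$period == p)
    row <- numeric(nv)
    row[ia] <- rowSums(act_hours[, sel, drop = FALSE])
    if (nf) row[iflow] <- rowSums(flow_hours[, sel, drop = FALSE])
    row[ih[sel]] <- -1
    A1 <- rbind(A1, row); b1 <- c(b1, unname(labour[p]))
    groups <- c(groups, paste0("labour:", p))
  }
  for (r in seq_len(ns)) {
    row <- numeric(nv)
    row[ia] <- -act_hours[, r]
    if (nf) row[iflow] <- -flow_hours[, r]
    row[ih[r]] <- 1
    A1 <- rbind(A1, row); b1 <- c(b1, 0)
    groups <- c(groups, paste0("hire_bound:", slots$key[r]))
  }

  # objective with a deterministic tie-break toward low activity index
  eps <- 1e-7 * seq_len(na)
  obj <- numeric(nv)
  maxi <- objective != "min_GHG"
  if (objective == "max_GM") {
    obj[ia] <- acts$gm - eps
    obj[ih] <- -slots$fee
  } else if (objective == "max_NE") {
    obj[ia] <- acts$ne - eps
    obj[ih] <- -1e-6
  } else {
    obj[ia] <- acts$ghg + eps
    obj[ih] <- 1e-6
  }

  program <- structure(list(
    tillage = tillage, year = year, objective = objective, options = opt,
    activities = acts, flows = flows, slots = slots, labour = labour,
    act_hours = act_hours, flow_hours = flow_hours,
    obj = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = maxi,
    greening = FALSE, bundle = bundle,
    idx = list(act = ia, flow = iflow, hire = ih)
  ), class = "farm_program")
  if (isTRUE(opt$greening)) program <- apply_greening(program)
  program
}

#' Add CAP-Greening constraints to a farm programme
#'
#' For every unordered pair of crop species, the combined area may not
#' exceed 95% of the farm area. With the land balance fixing total area,
#' the pairwise caps simultaneously force at least three species to be
#' grown (the third-largest must take at least 5% of the land).
#'
#' @param program A `farm_program`.
#' @return The programme with Greening rows appended.
#' @export
apply_greening <- function(program) {
  if (program$greening) return(program)
  acts <- program$activities
  species <- unique(acts$species)
  cap <- 0.95 * program$bundle$resources$area_ha
  nv <- length(program$obj)
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    row <- numeric(nv)
    row[program$idx$act[acts$species %in% c(species[i], species[j])]] <- 1
    program$A1 <- rbind(program$A1, row)
    program$b1 <- c(program$b1, cap)
  }
  program$greening <- TRUE
  program
}

#' Solve a farm programme
#'
#' Solves the linear programme with a two-phase simplex, then derives the
#' farm solution: activity areas, rotation flows, a deterministic
#' minimal-hire split of required hours into own-machine and contracted
#' hours (cheapest class hired first when labour binds), and all three
#' metrics (GM, NE, GHG) recomputed from areas times the coefficient
#' table regardless of which was optimised.
#'
#' @param program A `farm_program` (see [build_program()]).
#' @return An object of class `farm_solution`.
#' @export
solve_program <- function(program) {
  if (program$greening && length(unique(program$activities$species)) < 3)
    stop("infeasible: Greening constraint group (pairwise species caps ",
         "require at least three species; fewer are available)")
  s <- boot::simplex(a = program$obj, A1 = program$A1, b1 = program$b1,
                     A3 = program$A3, b3 = program$b3, maxi = program$maxi,
                     n.iter = 50 * length(program$obj), eps = 1e-9)
  if (s$solved == -1) {
    grp <- if (program$greening) "Greening/rotation/land" else "rotation/land/resource"
    stop("infeasible farm programme; binding constraint group: ", grp)
  }
  if (s$solved != 1) stop("LP solver did not converge")

  x <- s$soln
  acts <- program$activities
  areas <- pmax(x[program$idx$act], 0)
  names(areas) <- acts$activity
  flows <- program$flows
  if (nrow(flows)) flows$ha <- pmax(x[program$idx$flow], 0)

  # deterministic minimal-hire split
  slots <- program$slots
  req <- as.numeric(crossprod(program$act_hours, areas))
  if (nrow(flows)) req <- req + as.numeric(crossprod(program$flow_hours, flows$ha))
  own <- pmin(req, slots$cap)
  for (p in unique(slots$period)) {
    sel <- which(slots$period == p)
    lab <- program$labour[p]
    excess <- sum(own[sel]) - lab
    if (excess > 1e-9) {
      for (k in sel[order(slots$fee[sel])]) {
        take <- min(own[k], excess)
        own[k] <- own[k] - take
        excess <- excess - take
        if (excess <= 1e-9) break
      }
    }
  }
  hire <- pmax(req - own, 0)
  hire_cost <- sum(hire * slots$fee)

  gm <- sum(areas * acts$gm) - hire_cost
  ne <- sum(areas * acts$ne)
  ghg <- sum(areas * acts$ghg)

  species_area <- tapply(areas, acts$species, sum)

  # op-level required hours (for machinery complement sizing)
  op_rows <- list()
  for (i in seq_len(nrow(acts))) {
    if (areas[i] <= 1e-9) next
    ops <- inseason_ops(program$bundle, acts$crop[i], acts$straw[i])
    ops <- ops[!ops$contract, , drop = FALSE]
    if (nrow(ops)) {
      ops$hours <- ops$hours * areas[i]
      op_rows[[length(op_rows) + 1]] <- ops[, c("op", "implement", "power",
                                                "class", "period", "hours")]
    }
  }
  if (nrow(flows)) for (i in seq_len(nrow(flows))) {
    if (flows$ha[i] <= 1e-9) next
    est <- establishment_ops(program$bundle, program$tillage, flows$to[i])
    if (is.null(est)) next
    est$period <- flows$period[i]
    est$hours <- est$hours * flows$ha[i]
    op_rows[[length(op_rows) + 1]] <- est[, c("op", "implement", "power",
                                              "class", "period", "hours")]
  }
  op_hours <- if (length(op_rows)) {
    oh <- do.call(rbind, op_rows)
    stats::aggregate(hours ~ op + implement + power + class + period, oh, sum)
  } else data.frame(op = character(0), implement = character(0),
                    power = character(0), class = character(0),
                    period = character(0), hours = numeric(0))
  # own fraction per slot
  own_frac <- ifelse(req > 0, own / req, 1)
  names(own_frac) <- slots$key
  if (nrow(op_hours)) {
    key <- paste(op_hours$class, op_hours$period, sep = ".")
    op_hours$own_hours <- op_hours$hours * own_frac[key]
  } else op_hours$own_hours <- numeric(0)

  objective_value <- switch(program$objective,
                            max_GM = gm, max_NE = ne, min_GHG = ghg)

  structure(list(
    tillage = program$tillage, year = program$year,
    objective = program$objective, greening = program$greening,
    status = "optimal", objective_value = objective_value,
    areas = areas, species_area = c(species_area),
    flows = flows, activities = acts,
    gm = gm, ne = ne, ghg = ghg,
    fuel_l = sum(areas * acts$fuel_l),
    output_t = sum(areas * acts$output_t),
    kcal = sum(areas * acts$kcal),
    contract_fixed = sum(areas * acts$cost_contract),
    hire = data.frame(slots[, c("class", "period", "fee")],
                      required_h = req, own_h = own, hire_h = hire),
    hire_cost = hire_cost,
    contractor_fees = hire_cost + sum(areas * acts$cost_contract),
    own_hours_total = sum(own),
    op_hours = op_hours,
    area_ha = program$bundle$resources$area_ha
  ), class = "farm_solution")
}

#' @rdname solve_program
#' @param a A `farm_program` (for the `solve` method).
#' @param b Ignored.
#' @param ... Ignored.
#' @export
solve.farm_program <- function(a, b, ...) solve_program(a)

#' Convenience wrapper: build and solve in one call
#'
#' @inheritParams build_program
#' @return A `farm_solution`.
#' @export
optimize_farm <- function(bundle, tillage, year = "2011",
                          objective = "max_GM", options = list()) {
  solve_program(build_program(bundle, tillage, year, objective, options))
}

#' @export
print.farm_solution <- function(x, ...) {
  cat("<farm_solution> ", x$tillage, " / ", x$objective, " / ", x$year,
      if (x$greening) " / greening", "\n", sep = "")
  nz <- x$areas[x$areas > 1e-6]
  for (i in seq_along(nz))
    cat(sprintf("  %-14s %8.2f ha\n", names(nz)[i], nz[i]))
  cat(sprintf("  GM  %12.0f GBP/farm\n", x$gm))
  cat(sprintf("  NE  %12.1f GJ/farm\n", x$ne / 1000))
  cat(sprintf("  GHG %12.0f kg CO2-eq/farm\n", x$ghg))
  cat(sprintf("  fuel %11.0f L/farm, contractor fees %.0f GBP\n",
              x$fuel_l, x$contractor_fees))
  invisible(x)
}

#' Write a farm solution as CSV (crop-mix layout) and JSON
#'
#' The CSV mirrors the reporting layout of the model's crop-mix tables:
#' activity rows (with straw-fate and N-level key) followed by the three
#' metric rows; the JSON carries the full machine-readable solution.
#'
#' @param solution A `farm_solution`.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the crop-mix data frame.
#' @export
write_solution <- function(solution, csv = NULL, json = NULL) {
  nz <- solution$areas[solution$areas > 1e-6]
  acts <- solution$activities[match(names(nz), solution$activities$activity), ]
  lab <- sprintf("%s (%s, %d%% N)", acts$crop,
                 ifelse(acts$straw == "SR", "SR",
                        ifelse(acts$straw == "INC", "inc", "-")),
                 round(acts$n_level * 100))
  mix <- data.frame(row = c(lab,
                            "Gross margin (GBP/farm)",
                            "Net energy (GJ/farm)",
                            "GHG emissions (kg CO2-eq/farm)"),
                    value = c(round(unname(nz), 2),
                              round(solution$gm, 0),
                              round(solution$ne / 1000, 0),
                              round(solution$ghg, 0)))
  if (!is.null(csv)) utils::write.csv(mix, csv, row.names = FALSE)
  if (!is.null(json)) {
    out <- solution
    out$activities <- NULL
    out$op_hours <- NULL
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(mix)
}
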