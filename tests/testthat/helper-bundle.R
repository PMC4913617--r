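# Shared fixture: the shipped calibration, loaded once, plus a memoised
# solver so repeated tests of the same farm programme do not re-solve it.

the_bundle <- paperlike_calibration()

.solution_cache <- new.env(parent = emptyenv())

cached_solution <- function(tillage, objective = "max_GM", year = "2011",
                            greening = FALSE, bundle = the_bundle,
                            key_extra = "") {
  key <- paste(tillage, objective, year, greening, key_extra, sep = "|")
  if (!is.null(.solution_cache[[key]])) return(.solution_cache[[key]])
  sol <- optimize_farm(bundle, tillage, year, objective,
                       options = list(greening = greening))
  .solution_cache[[key]] <- sol
  sol
}

all_tillages <- c("CT", "RP", "DRT", "SRT1", "SRT2", "ZT")

# independent rotation-feasibility oracle: areas per crop are feasible in
# steady state iff the circulation with node throughputs saturates, checked
# with a max-flow algorithm (igraph), not with the LP solver
rotation_feasible_maxflow <- function(bundle, areas) {
  crops <- names(areas)
  ro <- bundle$rotation
  ro <- ro[ro$from %in% crops & ro$to %in% crops, ]
  n <- length(crops)
  # nodes: 1 = source, 2 = sink, then "out" side, then "in" side
  edges <- c(); caps <- c()
  for (i in seq_len(n)) {
    edges <- c(edges, 1, 2 + i)          # source -> out_i
    caps <- c(caps, areas[i])
    edges <- c(edges, 2 + n + i, 2)      # in_i -> sink
    caps <- c(caps, areas[i])
  }
  for (k in seq_len(nrow(ro))) {
    i <- match(ro$from[k], crops); j <- match(ro$to[k], crops)
    edges <- c(edges, 2 + i, 2 + n + j)
    caps <- c(caps, sum(areas))
  }
  gr <- igraph::make_graph(edges, n = 2 + 2 * n, directed = TRUE)
  mf <- igraph::max_flow(gr, source = 1, target = 2, capacity = caps)
  mf$value >= sum(areas) - 1e-7
}

# brute-force grid oracle for small instances: enumerate crop areas on a
# 1 ha grid, check rotation feasibility by max flow, and score each point
# with the best per-crop activity GM (resources unconstrained)
grid_oracle_gm <- function(bundle, crops, tillage, year = "2011") {
  tab <- activity_table(bundle, tillage, year, crops = crops)
  best <- tapply(tab$gm, tab$crop, max)[crops]
  area <- bundle$resources$area_ha
  pts <- expand.grid(x = 0:area, y = 0:area)
  pts <- pts[pts$x + pts$y <= area, ]
  pts$z <- area - pts$x - pts$y
  pts$val <- pts$x * best[1] + pts$y * best[2] + pts$z * best[3]
  pts <- pts[order(-pts$val), ]
  # points are scanned in decreasing value: the first rotation-feasible one
  # is the brute-force maximum
  for (i in seq_len(nrow(pts))) {
    a <- stats::setNames(unlist(pts[i, c("x", "y", "z")]), crops)
    if (rotation_feasible_maxflow(bundle, a)) return(pts$val[i])
  }
  -Inf
}
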