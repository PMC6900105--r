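# The 3D route graph: lattice nodes inside a migratory corridor at multiple
# pressure levels, travel-time edge weights under time-matched winds, and
# minimal flight time by shortest-path search.

DEG_M <- pi * EARTH_RADIUS_M / 180  # metres per great-circle degree

snap_to_lattice <- function(x, resolution = 0.4) {
  round(x / resolution) * resolution
}

node_key <- function(ila, ilo, ile) {
  paste(ila, ilo, ile, sep = ":")
}

#' Build the uninformed 3D node grid
#'
#' Lattice positions at `resolution` degrees inside the corridor polygon,
#' replicated over the configured pressure levels. Movements connect the 8
#' horizontal lattice neighbours, each at the same level or one layer up or
#' down; purely vertical moves are not allowed (they would be zero-cost).
#' Boundary nodes simply have fewer successors.
#'
#' @param corridor Data frame with columns `lat`, `lon`: vertices of a
#'   simple polygon covering the migratory zone (boundary inclusive).
#' @param resolution Lattice spacing in degrees (default 0.4).
#' @param levels Pressure levels in mb (strictly decreasing subset of the
#'   16 standard layers); `levels[1]` is treated as ground level.
#' @param require_nodes Optional data frame with `lat`, `lon` of positions
#'   (e.g. departure and arrival) that must snap to a node inside the
#'   corridor; a violation is a construction error.
#' @return An object of class `node_grid` with `nodes` (data.frame:
#'   `id`, `lat`, `lon`, `level`, level index `li`), a directed edge table
#'   (`from`, `to`, `dist_m`, `bearing_deg`) and `variant = "uninformed"`.
#' @export
build_grid <- function(corridor, resolution = 0.4,
                       levels = c(1000, 925, 850, 775),
                       require_nodes = NULL) {
  stopifnot(all(c("lat", "lon") %in% names(corridor)), nrow(corridor) >= 3)
  if (any(!(levels %in% ALLOWED_LEVELS)) || any(diff(levels) >= 0)) {
    stop("levels must be a strictly decreasing subset of the standard layers")
  }
  lat_idx <- seq(ceiling(min(corridor$lat) / resolution - 1e-9),
                 floor(max(corridor$lat) / resolution + 1e-9))
  lon_idx <- seq(ceiling(min(corridor$lon) / resolution - 1e-9),
                 floor(max(corridor$lon) / resolution + 1e-9))
  cells <- expand.grid(ila = lat_idx, ilo = lon_idx)
  inside <- pracma::inpolygon(round(cells$ilo * resolution, 10),
                              round(cells$ila * resolution, 10),
                              corridor$lon, corridor$lat, boundary = TRUE)
  cells <- cells[inside, , drop = FALSE]
  if (nrow(cells) == 0L) stop("corridor polygon contains no lattice nodes")

  nl <- length(levels)
  nodes <- data.frame(
    ila = rep(cells$ila, each = nl),
    ilo = rep(cells$ilo, each = nl),
    li = rep(seq_len(nl), times = nrow(cells)))
  nodes$lat <- round(nodes$ila * resolution, 10)
  nodes$lon <- round(nodes$ilo * resolution, 10)
  nodes$level <- levels[nodes$li]
  # deterministic node order: lat, then lon, then level index (descending mb)
  nodes <- nodes[order(nodes$lat, nodes$lon, nodes$li), , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL

  if (!is.null(require_nodes)) {
    for (i in seq_len(nrow(require_nodes))) {
      sla <- round(require_nodes$lat[i] / resolution)
      slo <- round(require_nodes$lon[i] / resolution)
      if (!any(nodes$ila == sla & nodes$ilo == slo)) {
        stop("corridor excludes required node at (",
             require_nodes$lat[i], ", ", require_nodes$lon[i], ")")
      }
    }
  }

  key <- node_key(nodes$ila, nodes$ilo, nodes$li)
  lookup <- stats::setNames(nodes$id, key)
  off <- expand.grid(dla = -1:1, dlo = -1:1, dli = -1:1)
  off <- off[!(off$dla == 0 & off$dlo == 0), , drop = FALSE]  # no vertical-only
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    tk <- node_key(nodes$ila + off$dla[k], nodes$ilo + off$dlo[k],
                   nodes$li + off$dli[k])
    hit <- lookup[tk]
    ok <- !is.na(hit)
    from <- c(from, nodes$id[ok])
    to <- c(to, unname(hit[ok]))
  }
  gc <- great_circle(nodes$lat[from], nodes$lon[from],
                     nodes$lat[to], nodes$lon[to])
  edges <- data.frame(from = from, to = to,
                      dist_m = gc$distance_m, bearing_deg = gc$bearing_deg)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes[, c("id", "lat", "lon", "level", "li",
                                   "ila", "ilo")],
                 edges = edges, levels = levels, resolution = resolution,
                 corridor = corridor, variant = "uninformed"),
            class = "node_grid")
}

#' @export
print.node_grid <- function(x, ...) {
  cat("<node_grid> ", nrow(x$nodes), " nodes (", x$variant, "), ",
      nrow(x$edges), " directed edges, ", length(x$levels),
      " levels, ", x$resolution, " deg\n", sep = "")
  invisible(x)
}

#' Restrict a grid to a corridor around retrieved in-flight locations
#'
#' The informed grid keeps only nodes within `buffer` great-circle degrees
#' of the piecewise-linear interpolation of the ordered in-flight fixes
#' (all pressure levels retained, since Argos fixes carry no altitude).
#' Departure/arrival positions passed via `keep` are always retained. By
#' construction the informed node set is a subset of the uninformed one.
#'
#' @param grid An uninformed [build_grid()] result.
#' @param fixes Data frame with `lat`, `lon` (and optionally `timestamp`,
#'   used for ordering) of the in-flight locations, at least one row.
#' @param buffer Constraint radius in great-circle degrees (default 0.5).
#' @param keep Optional data frame (`lat`, `lon`) of positions whose
#'   lattice cells are always kept (e.g. departure/arrival).
#' @return A `node_grid` with `variant = "informed"`.
#' @export
restrict_informed <- function(grid, fixes, buffer = 0.5, keep = NULL) {
  stopifnot(inherits(grid, "node_grid"), nrow(fixes) >= 1)
  if (!is.null(fixes$timestamp)) fixes <- fixes[order(fixes$timestamp), ]
  pts <- interpolate_track(fixes$lat, fixes$lon, step_deg = 0.1)

  cells <- unique(grid$nodes[, c("ila", "ilo")])
  cl_lat <- cells$ila * grid$resolution
  cl_lon <- cells$ilo * grid$resolution
  mind <- rep(Inf, nrow(cells))
  for (j in seq_len(nrow(pts))) {
    d <- great_circle(cl_lat, cl_lon, pts$lat[j], pts$lon[j])$distance_m
    mind <- pmin(mind, d / DEG_M)
  }
  ok_cell <- mind <= buffer
  keep_key <- character(0)
  if (!is.null(keep)) {
    keep_key <- paste(round(keep$lat / grid$resolution),
                      round(keep$lon / grid$resolution))
  }
  cell_key <- paste(cells$ila, cells$ilo)
  ok_cell <- ok_cell | cell_key %in% keep_key
  ok_keys <- cell_key[ok_cell]
  node_ok <- paste(grid$nodes$ila, grid$nodes$ilo) %in% ok_keys

  nodes <- grid$nodes[node_ok, , drop = FALSE]
  id_ok <- grid$nodes$id[node_ok]
  edges <- grid$edges[grid$edges$from %in% id_ok & grid$edges$to %in% id_ok, ,
                      drop = FALSE]
  # re-index ids to 1..n preserving the deterministic node order
  remap <- integer(max(grid$nodes$id))
  remap[nodes$id] <- seq_len(nrow(nodes))
  nodes$id <- seq_len(nrow(nodes))
  edges$from <- remap[edges$from]
  edges$to <- remap[edges$to]
  rownames(nodes) <- rownames(edges) <- NULL

  out <- grid
  out$nodes <- nodes
  out$edges <- edges
  out$variant <- "informed"
  out
}

interpolate_track <- function(lat, lon, step_deg = 0.1) {
  if (length(lat) == 1L) return(data.frame(lat = lat, lon = lon))
  out_lat <- numeric(0); out_lon <- numeric(0)
  for (i in seq_len(length(lat) - 1L)) {
    seg <- sqrt((lat[i + 1] - lat[i])^2 + (lon[i + 1] - lon[i])^2)
    np <- max(2L, ceiling(seg / step_deg) + 1L)
    f <- seq(0, 1, length.out = np)
    out_lat <- c(out_lat, lat[i] + f * (lat[i + 1] - lat[i]))
    out_lon <- c(out_lon, lon[i] + f * (lon[i + 1] - lon[i]))
  }
  data.frame(lat = out_lat, lon = out_lon)
}

#' Match a node to a 6-hourly wind analysis time
#'
#' The analysis time for a node is the one nearest to the estimated arrival
#' time at that node, where the estimate is the departure time plus the
#' still-air flight time of the straight line from the departure node.
#' This makes each node's wind static for a given departure, so the graph
#' has fixed weights and plain Dijkstra search is exact for this model.
#' Exact ties resolve to the earlier analysis.
#'
#' @param node_lat,node_lon Node position(s), degrees (vectorised).
#' @param dep_lat,dep_lon Departure node position, degrees.
#' @param departure_time `POSIXct` UTC departure time.
#' @param policy An [airspeed_policy()].
#' @param times Optional `POSIXct` vector of available analysis times to
#'   snap to; if `NULL`, snaps to the global 6-hourly synoptic grid.
#' @return `POSIXct` vector of matched analysis times.
#' @export
match_wind_time <- function(node_lat, node_lon, dep_lat, dep_lon,
                            departure_time, policy = airspeed_policy(),
                            times = NULL) {
  d <- great_circle(dep_lat, dep_lon, node_lat, node_lon)$distance_m
  est <- as.numeric(departure_time) + d / policy$airspeed
  if (is.null(times)) {
    snapped <- round(est / 21600) * 21600
    # round() half-to-even can land either side; force ties to the earlier one
    tie <- abs(est / 21600 - floor(est / 21600) - 0.5) < 1e-12
    snapped[tie] <- floor(est[tie] / 21600) * 21600
    return(as.POSIXct(snapped, tz = "UTC", origin = "1970-01-01"))
  }
  ft <- as.numeric(times)
  idx <- nearest_index(est, ft)
  as.POSIXct(ft[idx], tz = "UTC", origin = "1970-01-01")
}

resolve_node <- function(grid, lat, lon, level = NULL) {
  li <- if (is.null(level)) 1L else match(level, grid$levels)
  if (is.na(li)) stop("level ", level, " not in grid")
  ila <- round(lat / grid$resolution)
  ilo <- round(lon / grid$resolution)
  hit <- which(grid$nodes$ila == ila & grid$nodes$ilo == ilo &
               grid$nodes$li == li)
  if (length(hit) != 1L) {
    stop("position (", lat, ", ", lon, ") does not snap to a grid node")
  }
  grid$nodes$id[hit]
}

# Dijkstra with deterministic tie-breaking: minimal cost, then fewest edges,
# then smallest predecessor id (=> lexicographically smallest reversed node
# sequence). All edge weights are strictly positive, so predecessors of a
# node are always settled before the node itself and ties are final at pop.
dijkstra_core <- function(n, edges_from, edges_to, w, src, dst) {
  o <- order(edges_from, edges_to)
  ef <- edges_from[o]; et <- edges_to[o]; ew <- w[o]
  cnt <- tabulate(ef, nbins = n)
  ptr <- c(1L, 1L + cumsum(cnt))

  dist <- rep(Inf, n); nedge <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  dist[src] <- 0; nedge[src] <- 0
  dtmp <- dist
  repeat {
    u <- which.min(dtmp)
    du <- dtmp[u]
    if (!is.finite(du)) break
    dtmp[u] <- Inf
    if (u == dst) break
    j0 <- ptr[u]; j1 <- ptr[u + 1L] - 1L
    if (j1 < j0) next
    js <- j0:j1
    vs <- et[js]
    nd <- du + ew[js]
    fin <- is.finite(nd)
    if (!any(fin)) next
    vs <- vs[fin]; nd <- nd[fin]
    eps <- 1e-9 * (1 + nd)
    better <- nd < dist[vs] - eps
    tie <- abs(nd - dist[vs]) <= eps
    ne_new <- nedge[u] + 1
    tb <- tie & ne_new < nedge[vs]
    tb2 <- tie & ne_new == nedge[vs] & !is.na(pred[vs]) & u < pred[vs]
    upd <- better | tb | tb2
    if (any(upd)) {
      tv <- vs[upd]
      dist[tv] <- nd[upd]
      nedge[tv] <- ne_new
      pred[tv] <- u
      # only not-yet-settled nodes can appear here (positive weights)
      dtmp[tv] <- nd[upd]
    }
  }
  list(dist = dist, pred = pred, nedge = nedge)
}

node_wind <- function(grid, field, dep_lat, dep_lon, departure_time, policy) {
  tm <- match_wind_time(grid$nodes$lat, grid$nodes$lon, dep_lat, dep_lon,
                        departure_time, policy, times = field$times)
  sample_wind(field, grid$nodes$lat, grid$nodes$lon, grid$nodes$level, tm)
}

edge_weights <- function(grid, wind, policy) {
  src <- grid$edges$from
  wc <- wind_components(wind$u[src], wind$v[src], grid$edges$bearing_deg)
  g <- groundspeed(wc$tailwind, wc$crosswind, policy)
  w <- grid$edges$dist_m / g
  w[is.na(w)] <- Inf
  w
}

#' Minimal flight time through the grid
#'
#' Finds the minimum-total-travel-time path from the departure node to the
#' arrival node. Node winds are sampled at the analysis time matched by
#' [match_wind_time()]; each edge is weighted by [edge_travel_time()]
#' using the wind at its origin node. Ties are broken by fewer edges, then
#' by lexicographic node order, so the output is deterministic.
#'
#' @param grid A [build_grid()] or [restrict_informed()] result.
#' @param field A [wind_field()] covering the grid.
#' @param departure,arrival Lists with `lat`, `lon` and optional `level`
#'   (mb; default the grid's ground level). Must resolve to grid nodes.
#' @param departure_time `POSIXct` UTC.
#' @param policy An [airspeed_policy()].
#' @return An object of class `route_result`: `total_time_h`, `path`
#'   (data.frame of nodes in order), `per_edge_times_s`, `variant`,
#'   `departure_time`, `reachable`. If every cut is infeasible the result
#'   has `reachable = FALSE` and infinite time.
#' @export
minimal_flight_time <- function(grid, field, departure, arrival,
                                departure_time, policy = airspeed_policy()) {
  src <- resolve_node(grid, departure$lat, departure$lon, departure$level)
  dst <- resolve_node(grid, arrival$lat, arrival$lon, arrival$level)
  dep_lat <- grid$nodes$lat[src]; dep_lon <- grid$nodes$lon[src]
  wind <- node_wind(grid, field, dep_lat, dep_lon, departure_time, policy)
  w <- edge_weights(grid, wind, policy)
  res <- dijkstra_core(nrow(grid$nodes), grid$edges$from, grid$edges$to, w,
                       src, dst)
  build_route_result(grid, res, src, dst, departure_time)
}

build_route_result <- function(grid, res, src, dst, departure_time) {
  if (!is.finite(res$dist[dst])) {
    return(structure(list(total_time_h = Inf, path = NULL,
                          per_edge_times_s = numeric(0),
                          variant = grid$variant,
                          departure_time = departure_time,
                          reachable = FALSE),
                     class = "route_result"))
  }
  ids <- dst
  while (ids[1] != src) ids <- c(res$pred[ids[1]], ids)
  per_edge <- diff(res$dist[ids])
  structure(list(total_time_h = res$dist[dst] / 3600,
                 path = grid$nodes[match(ids, grid$nodes$id),
                                   c("id", "lat", "lon", "level")],
                 per_edge_times_s = per_edge,
                 variant = grid$variant,
                 departure_time = departure_time,
                 reachable = TRUE),
            class = "route_result")
}

#' @export
print.route_result <- function(x, ...) {
  if (!x$reachable) {
    cat("<route_result> unreachable (", x$variant, " grid)\n", sep = "")
  } else {
    cat(sprintf("<route_result> %.2f h over %d edges (%s grid), departing %s UTC\n",
                x$total_time_h, length(x$per_edge_times_s), x$variant,
                format(x$departure_time, tz = "UTC")))
  }
  invisible(x)
}

#' Arrival node for a bird that died in flight
#'
#' For fatal crossings the arrival node cannot be observed; following the
#' high staging-site fidelity of adult godwits, the arrival node of the
#' most recent previously completed northward crossing is substituted.
#'
#' @param history Data frame of the individual's prior crossings with
#'   columns `season`, `departure_time`, `arr_lat`, `arr_lon`, `complete`
#'   (logical).
#' @return A list with `lat`, `lon` of the substituted arrival node, or a
#'   `crossing_exclusion` object (with element `reason`) when no prior
#'   completed northward crossing exists and the crossing must be excluded.
#' @export
arrival_node_for_dead_bird <- function(history) {
  cand <- history[history$season == "northward" & history$complete, ,
                  drop = FALSE]
  if (nrow(cand) == 0L) {
    return(structure(list(reason = "no prior completed northward crossing"),
                     class = "crossing_exclusion"))
  }
  cand <- cand[order(cand$departure_time), , drop = FALSE]
  last <- cand[nrow(cand), ]
  list(lat = last$arr_lat, lon = last$arr_lon)
}

#' Simulate minimal routes for a table of crossings
#'
#' Convenience driver: builds the uninformed grid once, then computes the
#' minimal flight time for each crossing, optionally restricting to the
#' informed grid around that crossing's in-flight fixes.
#'
#' @param crossings Data frame with columns `crossing_id`, `individual`,
#'   `season`, `dep_lat`, `dep_lon`, `dep_time` (`POSIXct` UTC),
#'   `arr_lat`, `arr_lon`.
#' @param field A [wind_field()] (or a named list of fields keyed by
#'   season, e.g. from [generate_seasonal_scenario()]).
#' @param corridor Corridor polygon (data frame `lat`, `lon`).
#' @param levels Pressure levels for the grid.
#' @param resolution Lattice spacing, degrees.
#' @param variant `"uninformed"` or `"informed"`.
#' @param fix_list For the informed variant, a named list (by
#'   `crossing_id`) of in-flight fix data frames (`lat`, `lon`,
#'   `timestamp`).
#' @param buffer Informed constraint radius, great-circle degrees.
#' @param policy An [airspeed_policy()].
#' @return Data frame: `crossing_id`, `individual`, `season`, `variant`,
#'   `total_time_h`, `n_edges`, `reachable`.
#' @export
simulate_routes <- function(crossings, field, corridor,
                            levels = c(1000, 925, 850, 775),
                            resolution = 0.4,
                            variant = c("uninformed", "informed"),
                            fix_list = NULL, buffer = 0.5,
                            policy = airspeed_policy()) {
  variant <- match.arg(variant)
  grid <- build_grid(corridor, resolution, levels)
  out <- vector("list", nrow(crossings))
  for (i in seq_len(nrow(crossings))) {
    cr <- crossings[i, ]
    fld <- if (inherits(field, "wind_field")) field else field[[cr$season]]
    g <- grid
    if (variant == "informed") {
      fx <- fix_list[[as.character(cr$crossing_id)]]
      if (is.null(fx) || nrow(fx) == 0L) {
        stop("informed variant needs >= 1 in-flight fix for crossing ",
             cr$crossing_id)
      }
      if (!is.null(fx$timestamp)) fx <- fx[order(fx$timestamp), ]
      # the constrained route runs from the departure node through the
      # retrieved locations to the arrival node
      poly <- rbind(data.frame(lat = cr$dep_lat, lon = cr$dep_lon),
                    fx[, c("lat", "lon")],
                    data.frame(lat = cr$arr_lat, lon = cr$arr_lon))
      g <- restrict_informed(grid, poly, buffer = buffer,
                             keep = data.frame(lat = c(cr$dep_lat, cr$arr_lat),
                                               lon = c(cr$dep_lon, cr$arr_lon)))
    }
    rr <- minimal_flight_time(g, fld,
                              departure = list(lat = cr$dep_lat, lon = cr$dep_lon),
                              arrival = list(lat = cr$arr_lat, lon = cr$arr_lon),
                              departure_time = cr$dep_time, policy = policy)
    out[[i]] <- data.frame(crossing_id = cr$crossing_id,
                           individual = cr$individual,
                           season = cr$season, variant = variant,
                           total_time_h = rr$total_time_h,
                           n_edges = length(rr$per_edge_times_s),
                           reachable = rr$reachable)
  }
  do.call(rbind, out)
}
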