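# Independent shortest-path oracle: exhaustive simple-path enumeration with
# an admissible straight-line lower bound (prunes only provably worse
# prefixes, so the search remains exact), applying the same tie-break
# definition as the package: minimal cost, then fewest edges, then
# lexicographically smallest reversed node sequence.

# lb: admissible per-node lower bound on remaining cost to dst (0 is valid)
oracle_best_path <- function(n, edges, w, src, dst, lb = rep(0, n)) {
  adj <- split(seq_along(edges$from), factor(edges$from, levels = seq_len(n)))
  env <- new.env()
  env$cost <- Inf
  env$path <- NULL

  replaces <- function(c_new, p_new, c_old, p_old) {
    eps <- 1e-9 * (1 + c_new)
    if (c_new < c_old - eps) return(TRUE)
    if (abs(c_new - c_old) > eps) return(FALSE)
    if (length(p_new) != length(p_old)) return(length(p_new) < length(p_old))
    r1 <- rev(p_new); r2 <- rev(p_old)
    d <- which(r1 != r2)
    if (length(d) == 0L) return(FALSE)
    r1[d[1]] < r2[d[1]]
  }

  onpath <- rep(FALSE, n)
  dfs <- function(u, cost, path) {
    if (cost + lb[u] > env$cost + 1e-9 * (1 + env$cost)) return(invisible())
    if (u == dst) {
      if (replaces(cost, path, env$cost, env$path)) {
        env$cost <- cost
        env$path <- path
      }
      return(invisible())
    }
    for (j in adj[[u]]) {
      v <- edges$to[j]
      if (onpath[v] || !is.finite(w[j])) next
      onpath[v] <<- TRUE
      dfs(v, cost + w[j], c(path, v))
      onpath[v] <<- FALSE
    }
    invisible()
  }
  onpath[src] <- TRUE
  dfs(src, 0, src)
  list(cost = env$cost, path = env$path)
}

# run the package's search and the oracle on the same grid/field/departure,
# returning both answers for comparison
compare_with_oracle <- function(grid, field, dep, arr, dep_time,
                                policy = airspeed_policy()) {
  rr <- minimal_flight_time(grid, field, dep, arr, dep_time, policy)
  src <- windcross:::resolve_node(grid, dep$lat, dep$lon, dep$level)
  dst <- windcross:::resolve_node(grid, arr$lat, arr$lon, arr$level)
  wind <- windcross:::node_wind(grid, field, grid$nodes$lat[src],
                                grid$nodes$lon[src], dep_time, policy)
  w <- windcross:::edge_weights(grid, wind, policy)
  wmax <- max(sqrt(field$u^2 + field$v^2))
  lb <- great_circle(grid$nodes$lat, grid$nodes$lon,
                     grid$nodes$lat[dst], grid$nodes$lon[dst])$distance_m /
    (policy$airspeed + wmax)
  or <- oracle_best_path(nrow(grid$nodes), grid$edges, w, src, dst, lb)
  list(dijkstra = rr, oracle = or)
}
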