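test_that("lattice construction matches expected node counts and connectivity", {
  levels16 <- c(1000, 975, 950, 925, 900, 875, 850, 825, 800, 775,
                750, 700, 650, 600, 550, 500)
  grid <- build_grid(box_corridor(0, 2, 0, 2), 0.4, levels16)
  expect_equal(nrow(grid$nodes), 6 * 6 * 16)   # both boundary lines included

  # interior node: 8 horizontal neighbours x 3 level choices
  mid <- grid$nodes$id[grid$nodes$lat == 0.8 & grid$nodes$lon == 0.8 &
                         grid$nodes$level == 850]
  expect_equal(sum(grid$edges$from == mid), 24)

  # top layer (500 mb, last level index) has no upward successors
  top <- grid$nodes$id[grid$nodes$level == 500]
  li_to <- grid$nodes$li[match(grid$edges$to[grid$edges$from %in% top],
                               grid$nodes$id)]
  expect_true(all(li_to >= 15))

  # no purely vertical edges anywhere
  same_cell <- grid$nodes$ila[match(grid$edges$from, grid$nodes$id)] ==
    grid$nodes$ila[match(grid$edges$to, grid$nodes$id)] &
    grid$nodes$ilo[match(grid$edges$from, grid$nodes$id)] ==
    grid$nodes$ilo[match(grid$edges$to, grid$nodes$id)]
  expect_false(any(same_cell))

  expect_error(build_grid(box_corridor(0, 2, 0, 2), 0.4, levels16,
                          require_nodes = data.frame(lat = 5, lon = 5)),
               "excludes required node")
})

test_that("zero wind gives time = lattice distance / airspeed on a straight chain", {
  grid <- chain_grid(1.6)           # 5 nodes along the equator
  fld <- const_field(0, 0, levels = 1000,
                     lats = seq(-0.4, 0.4, 0.4), lons = seq(-0.4, 2, 0.4))
  rr <- minimal_flight_time(grid, fld, list(lat = 0, lon = 0),
                            list(lat = 0, lon = 1.6), utc("2017-01-01 00:00:00"))
  d <- great_circle(0, 0, 0, 0.4)$distance_m
  expect_equal(rr$total_time_h, 4 * d / 18.05 / 3600, tolerance = 1e-9)
  expect_equal(nrow(rr$path), 5)
})

test_that("uniform tailwind scales chain time by airspeed/(airspeed+w)", {
  grid <- chain_grid(1.6)
  lats <- seq(-0.4, 0.4, 0.4); lons <- seq(-0.4, 2, 0.4)
  t0 <- minimal_flight_time(grid, const_field(0, 0, levels = 1000,
                                              lats = lats, lons = lons),
                            list(lat = 0, lon = 0), list(lat = 0, lon = 1.6),
                            utc("2017-01-01 00:00:00"))$total_time_h
  w <- 5
  tw <- minimal_flight_time(grid, const_field(w, 0, levels = 1000,
                                              lats = lats, lons = lons),
                            list(lat = 0, lon = 0), list(lat = 0, lon = 1.6),
                            utc("2017-01-01 00:00:00"))$total_time_h
  expect_equal(tw, t0 * 18.05 / (18.05 + w), tolerance = 1e-9)
})

test_that("an everywhere-infeasible headwind yields an explicit unreachable result", {
  grid <- chain_grid(1.6)
  fld <- const_field(-18.05, 0, levels = 1000,
                     lats = seq(-0.4, 0.4, 0.4), lons = seq(-0.4, 2, 0.4))
  rr <- minimal_flight_time(grid, fld, list(lat = 0, lon = 0),
                            list(lat = 0, lon = 1.6), utc("2017-01-01 00:00:00"))
  expect_false(rr$reachable)
  expect_identical(rr$total_time_h, Inf)
})

test_that("adding tailwind along the direction of travel never increases minimal time", {
  grid <- chain_grid(1.6)
  lats <- seq(-0.4, 0.4, 0.4); lons <- seq(-0.4, 2, 0.4)
  set.seed(3)
  base_u <- rnorm(1, 0, 3)
  t_prev <- Inf
  for (boost in c(0, 2, 4, 6)) {
    t_cur <- minimal_flight_time(grid,
                                 const_field(base_u + boost, 0, levels = 1000,
                                             lats = lats, lons = lons),
                                 list(lat = 0, lon = 0), list(lat = 0, lon = 1.6),
                                 utc("2017-01-01 00:00:00"))$total_time_h
    expect_lte(t_cur, t_prev)
    t_prev <- t_cur
  }
})

test_that("search agrees with igraph on random grids", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    fld <- random_field(seed)
    grid <- build_grid(box_corridor(0, 1.2, 0, 1.2), 0.4, c(1000, 975))
    dep <- list(lat = 0, lon = 0); arr <- list(lat = 1.2, lon = 1.2)
    dep_time <- utc("2017-01-01 00:00:00")
    rr <- minimal_flight_time(grid, fld, dep, arr, dep_time)

    src <- windcross:::resolve_node(grid, dep$lat, dep$lon, NULL)
    dst <- windcross:::resolve_node(grid, arr$lat, arr$lon, NULL)
    wind <- windcross:::node_wind(grid, fld, grid$nodes$lat[src],
                                  grid$nodes$lon[src], dep_time,
                                  airspeed_policy())
    w <- windcross:::edge_weights(grid, wind, airspeed_policy())
    ok <- is.finite(w)
    g <- igraph::graph_from_data_frame(
      data.frame(from = grid$edges$from[ok], to = grid$edges$to[ok]),
      directed = TRUE, vertices = data.frame(name = grid$nodes$id))
    d <- igraph::distances(g, v = as.character(src), to = as.character(dst),
                           mode = "out", weights = w[ok])
    expect_equal(rr$total_time_h, as.numeric(d) / 3600, tolerance = 1e-9)
  }
})

test_that("wind-time matching uses the straight-line arrival estimate", {
  dep_time <- utc("2017-04-10 00:00:00")
  times <- synoptic_times("2017-04-09 18:00:00", 10)

  # node = departure node: nearest analysis to the departure time itself
  expect_equal(match_wind_time(10, 0, 10, 0, dep_time, times = times),
               dep_time)

  # a node 650.7 km away: estimate = departure + 650700/18.05 s = +10.01 h
  d_deg <- 650700 / (pi * 6371000 / 180)
  mt <- match_wind_time(10 + d_deg, 0, 10, 0, dep_time, times = times)
  expect_equal(mt, utc("2017-04-10 12:00:00"))

  # equidistant nodes get identical matched times
  m2 <- match_wind_time(c(10, 10), c(2, -2), 10, 0, dep_time, times = times)
  expect_equal(m2[1], m2[2])

  # exact 3-h tie resolves to the earlier analysis
  d_tie <- (3 * 3600 * 18.05) / (pi * 6371000 / 180)
  expect_equal(match_wind_time(10 + d_tie, 0, 10, 0, dep_time, times = times),
               utc("2017-04-10 00:00:00"))
})

test_that("informed restriction keeps a corridor around the fixes and is a subset", {
  grid <- build_grid(box_corridor(0, 4, 0, 4), 0.4, c(1000, 975))
  fixes <- data.frame(lat = c(0.4, 2.0, 3.6), lon = c(0.4, 2.0, 3.6))

  inf <- restrict_informed(grid, fixes, buffer = 0.2)
  expect_true(all(inf$nodes$id %in% seq_len(nrow(inf$nodes))))
  expect_lt(nrow(inf$nodes), nrow(grid$nodes))
  expect_identical(inf$variant, "informed")
  # every kept cell lies within the buffer of the interpolated diagonal
  keys_uninf <- paste(grid$nodes$ila, grid$nodes$ilo, grid$nodes$li)
  keys_inf <- paste(inf$nodes$ila, inf$nodes$ilo, inf$nodes$li)
  expect_true(all(keys_inf %in% keys_uninf))   # subset, any inputs

  # all levels retained where a cell is kept (fixes carry no altitude)
  cells <- unique(inf$nodes[, c("ila", "ilo")])
  expect_equal(nrow(inf$nodes), nrow(cells) * 2)

  # buffer larger than the corridor diameter: informed == uninformed
  inf_all <- restrict_informed(grid, fixes, buffer = 1e6)
  expect_equal(nrow(inf_all$nodes), nrow(grid$nodes))
  expect_equal(nrow(inf_all$edges), nrow(grid$edges))
})

test_that("arrival node substitution for dead birds uses the most recent northward crossing", {
  h <- data.frame(season = c("northward", "northward"),
                  departure_time = utc(c("2015-04-10", "2016-04-12")),
                  arr_lat = c(37, 38.6), arr_lon = c(-8, -9),
                  complete = c(TRUE, TRUE))
  expect_equal(arrival_node_for_dead_bird(h), list(lat = 38.6, lon = -9))
  expect_equal(arrival_node_for_dead_bird(h[1, ]), list(lat = 37, lon = -8))

  none <- arrival_node_for_dead_bird(
    data.frame(season = "southward", departure_time = utc("2015-10-01"),
               arr_lat = 14, arr_lon = -16, complete = TRUE))
  expect_s3_class(none, "crossing_exclusion")
  expect_match(none$reason, "no prior")
})
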