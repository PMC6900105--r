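# Shared fixture builders: tiny wind fields and corridors constructed in
# code at test time.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# constant-wind field covering a small box
const_field <- function(u = 0, v = 0, n_times = 4,
                        start = "2017-01-01 00:00:00",
                        levels = c(1000, 925),
                        lats = seq(-2, 4, by = 0.4),
                        lons = seq(-2, 4, by = 0.4)) {
  times <- synoptic_times(start, n_times)
  dims <- c(n_times, length(levels), length(lats), length(lons))
  wind_field(times, levels, lats, lons,
             array(u, dim = dims), array(v, dim = dims))
}

# field with fully random winds (reproducible), for oracle comparisons
random_field <- function(seed, wind_sd = 4, n_times = 2,
                         levels = c(1000, 975),
                         lats = seq(-0.4, 1.6, by = 0.4),
                         lons = seq(-0.4, 1.6, by = 0.4)) {
  set.seed(seed)
  times <- synoptic_times("2017-01-01 00:00:00", n_times)
  dims <- c(n_times, length(levels), length(lats), length(lons))
  wind_field(times, levels, lats, lons,
             array(rnorm(prod(dims), 0, wind_sd), dim = dims),
             array(rnorm(prod(dims), 0, wind_sd), dim = dims))
}

box_corridor <- function(lat0, lat1, lon0, lon1) {
  data.frame(lat = c(lat0, lat0, lat1, lat1), lon = c(lon0, lon1, lon1, lon0))
}

# single-row eastbound chain of nodes at one level: lat 0, lon 0..lon_max
chain_grid <- function(lon_max = 1.6, levels = 1000) {
  build_grid(box_corridor(-0.1, 0.1, -0.05, lon_max + 0.05),
             resolution = 0.4, levels = levels)
}
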