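# 4D wind fields: container, validation, plain-text I/O, point queries and
# the synthetic trade-wind generator.

# Pressure layers available to the route grid (mb, decreasing = ascending).
# 1000 mb is near ground level, 500 mb roughly 5.5 km altitude, spanning the
# full altitudinal range observed for migrating godwits.
ALLOWED_LEVELS <- c(1000, 975, 950, 925, 900, 875, 850, 825, 800, 775,
                    750, 700, 650, 600, 550, 500)

SYNOPTIC_HOURS <- c(0, 6, 12, 18)

# parse ISO-8601 timestamps in UTC, accepting both "T" and space separators
parse_utc <- function(x) {
  y <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  bad <- is.na(y)
  if (any(bad)) y[bad] <- as.POSIXct(x[bad], tz = "UTC")
  y
}

#' Construct a 4D wind field
#'
#' Holds eastward (`u`) and northward (`v`) wind components on a regular
#' time x pressure-level x latitude x longitude grid, mirroring 6-hourly
#' atmospheric reanalysis products.
#'
#' @param times `POSIXct` (UTC) analysis times; must be exactly 6 h apart
#'   and fall on 00:00/06:00/12:00/18:00 UTC.
#' @param levels Pressure levels in mb, strictly decreasing, a subset of
#'   the 16 standard layers between 1000 and 500 mb.
#' @param lats,lons Regularly spaced coordinate vectors, degrees, increasing.
#' @param u,v Numeric arrays of dimension
#'   `c(length(times), length(levels), length(lats), length(lons))`, m/s,
#'   all finite.
#' @return An object of class `wind_field`.
#' @export
wind_field <- function(times, levels, lats, lons, u, v) {
  fld <- structure(list(times = times, levels = levels, lats = lats,
                        lons = lons, u = u, v = v),
                   class = "wind_field")
  validate_wind_field(fld)
  fld
}

validate_wind_field <- function(fld) {
  times <- fld$times
  if (!inherits(times, "POSIXct")) stop("wind field times must be POSIXct")
  if (length(times) < 1L) stop("wind field needs at least one analysis time")
  if (length(times) > 1L) {
    dt <- diff(as.numeric(times))
    if (any(dt != 21600)) {
      stop("wind field invariant violated: analysis times must be exactly 6 h apart")
    }
  }
  hrs <- as.integer(format(times, "%H", tz = "UTC"))
  mins <- as.integer(format(times, "%M", tz = "UTC"))
  if (any(!(hrs %in% SYNOPTIC_HOURS)) || any(mins != 0L)) {
    stop("wind field invariant violated: analysis times must fall on 0:00/6:00/12:00/18:00 UTC")
  }
  lv <- fld$levels
  if (any(!(lv %in% ALLOWED_LEVELS)) || any(diff(lv) >= 0)) {
    stop("wind field invariant violated: levels must be a strictly decreasing subset of the standard 1000-500 mb layers")
  }
  for (ax in c("lats", "lons")) {
    g <- fld[[ax]]
    if (length(g) < 1L) stop("empty coordinate axis: ", ax)
    if (length(g) > 2L) {
      sp <- diff(g)
      if (any(sp <= 0) || max(abs(sp - sp[1])) > 1e-8) {
        stop("wind field invariant violated: ", ax, " spacing must be uniform and increasing")
      }
    }
  }
  dims <- c(length(times), length(lv), length(fld$lats), length(fld$lons))
  for (comp in c("u", "v")) {
    a <- fld[[comp]]
    if (!is.array(a) || !identical(dim(a), as.integer(dims))) {
      stop("wind component ", comp, " must be an array of dim time x level x lat x lon")
    }
    if (any(!is.finite(a))) {
      stop("wind field invariant violated: non-finite values in ", comp)
    }
  }
  invisible(fld)
}

#' @export
print.wind_field <- function(x, ...) {
  cat("<wind_field> ", length(x$times), " times x ", length(x$levels),
      " levels x ", length(x$lats), " lats x ", length(x$lons), " lons\n",
      sep = "")
  cat("  time range: ", format(min(x$times), tz = "UTC"), " .. ",
      format(max(x$times), tz = "UTC"), " UTC\n", sep = "")
  cat("  levels (mb): ", paste(x$levels, collapse = ", "), "\n", sep = "")
  cat(sprintf("  lat [%g, %g], lon [%g, %g]\n", min(x$lats), max(x$lats),
              min(x$lons), max(x$lons)))
  invisible(x)
}

#' Read a gridded wind field from a long-format CSV file
#'
#' The file must contain the columns `time` (ISO-8601 UTC), `level` (mb),
#' `lat`, `lon` (degrees), `u`, `v` (m/s), with one row per grid cell and
#' a complete time x level x lat x lon grid. All `wind_field` invariants
#' are enforced; violations produce a format error naming the invariant.
#'
#' @param path Path to the CSV file.
#' @return A [wind_field()].
#' @seealso [write_wind_field()]
#' @export
load_wind_field <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "level", "lat", "lon", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("wind file is missing required component(s): ", paste(miss, collapse = ", "))
  }
  tparsed <- parse_utc(df$time)
  if (anyNA(tparsed)) stop("unparseable timestamps in wind file")
  times <- sort(unique(tparsed))
  levels <- sort(unique(df$level), decreasing = TRUE)
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  nt <- length(times); nl <- length(levels)
  nla <- length(lats); nlo <- length(lons)
  if (nrow(df) != nt * nl * nla * nlo) {
    stop("wind file grid is incomplete: expected ", nt * nl * nla * nlo,
         " rows for a full time x level x lat x lon grid, got ", nrow(df))
  }
  it <- match(as.numeric(tparsed), as.numeric(times))
  il <- match(df$level, levels)
  ia <- match(df$lat, lats)
  io <- match(df$lon, lons)
  u <- array(NA_real_, dim = c(nt, nl, nla, nlo))
  v <- array(NA_real_, dim = c(nt, nl, nla, nlo))
  idx <- cbind(it, il, ia, io)
  u[idx] <- df$u
  v[idx] <- df$v
  if (anyNA(u) || anyNA(v)) stop("wind file grid has duplicate or missing cells")
  wind_field(times, levels, lats, lons, u, v)
}

#' Write a wind field to the long-format CSV used by [load_wind_field()]
#'
#' @param fld A [wind_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wind_field <- function(fld, path) {
  validate_wind_field(fld)
  g <- expand.grid(ti = seq_along(fld$times), li = seq_along(fld$levels),
                   ai = seq_along(fld$lats), oi = seq_along(fld$lons))
  idx <- cbind(g$ti, g$li, g$ai, g$oi)
  df <- data.frame(
    time = format(fld$times[g$ti], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    level = fld$levels[g$li],
    lat = fld$lats[g$ai],
    lon = fld$lons[g$oi],
    u = fld$u[idx],
    v = fld$v[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

nearest_index <- function(x, grid) {
  # nearest grid index; exact ties resolve to the earlier/smaller entry
  i <- findInterval(x, grid, all.inside = TRUE)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(grid))
  ifelse(abs(x - grid[lo]) <= abs(grid[hi] - x), lo, hi)
}

#' Sample wind at a point, pressure level and time
#'
#' Nearest-neighbour lookup in latitude, longitude and level, matched with
#' the time-wise nearest 6-hourly analysis; an exact tie in time resolves
#' to the earlier analysis. Queries outside the spatial/level extent (with
#' half a grid cell of slack) raise an out-of-domain error.
#'
#' @param fld A [wind_field()].
#' @param lat,lon Query position, degrees (vectorised).
#' @param level Pressure level, mb.
#' @param t `POSIXct` UTC query time.
#' @return A list of numeric vectors `u`, `v` (m/s).
#' @export
sample_wind <- function(fld, lat, lon, level, t) {
  n <- max(length(lat), length(lon), length(level), length(t))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  level <- rep_len(level, n)
  tt <- rep_len(as.numeric(t), n)

  half <- function(g) if (length(g) > 1L) abs(g[2] - g[1]) / 2 else 0
  out <- lat < min(fld$lats) - half(fld$lats) | lat > max(fld$lats) + half(fld$lats) |
         lon < min(fld$lons) - half(fld$lons) | lon > max(fld$lons) + half(fld$lons) |
         level > max(fld$levels) | level < min(fld$levels)
  if (any(out)) {
    stop("wind query outside field domain (lat/lon/level extent)")
  }
  ia <- nearest_index(lat, fld$lats)
  io <- nearest_index(lon, fld$lons)
  # levels are stored decreasing; search on the reversed axis
  lv_inc <- rev(fld$levels)
  il <- length(fld$levels) + 1L - nearest_index(level, lv_inc)
  ft <- as.numeric(fld$times)
  it <- nearest_index(tt, ft)
  idx <- cbind(it, il, ia, io)
  list(u = fld$u[idx], v = fld$v[idx])
}

#' Configuration for the synthetic trade-wind generator
#'
#' Emulates the prevailing north-easterly trade winds over the Sahara:
#' a mean wind blowing toward the south-west (`mean_trade_u`,
#' `mean_trade_v` both negative), scaled per pressure level by
#' `shear_profile`, optionally flipped by `seasonal_reversal`, plus
#' temporally autocorrelated (AR(1)) noise of marginal standard deviation
#' `temporal_sd` shared across the grid.
#'
#' @param mean_trade_u,mean_trade_v Mean wind components, m/s. The defaults
#'   (-5, -4) give a ~6.4 m/s wind out of the north-east.
#' @param shear_profile Per-level multiplicative factors (recycled to the
#'   number of levels); default strengthens the flow aloft.
#' @param temporal_sd Marginal SD of the day-to-day noise, m/s; >= 0.
#' @param ar1 Lag-1 autocorrelation of the noise at 6-h spacing.
#' @param seasonal_reversal Factor applied to the mean components (e.g. -1
#'   to reverse the flow); 1 leaves the trades unchanged.
#' @param seed RNG seed; a fixed seed yields an identical field.
#' @return An object of class `synthetic_wind_config`.
#' @export
synthetic_wind_config <- function(mean_trade_u = -5, mean_trade_v = -4,
                                  shear_profile = c(0.8, 1.0, 1.2, 1.4),
                                  temporal_sd = 2, ar1 = 0.6,
                                  seasonal_reversal = 1, seed = 1L) {
  stopifnot(temporal_sd >= 0, abs(ar1) < 1)
  structure(list(mean_trade_u = mean_trade_u, mean_trade_v = mean_trade_v,
                 shear_profile = shear_profile, temporal_sd = temporal_sd,
                 ar1 = ar1, seasonal_reversal = seasonal_reversal,
                 seed = as.integer(seed)),
            class = "synthetic_wind_config")
}

#' Generate a synthetic trade-wind field
#'
#' @param cfg A [synthetic_wind_config()].
#' @param extent List with `lats` and `lons` coordinate vectors (uniform
#'   spacing) covering the simulation corridor.
#' @param times `POSIXct` UTC analysis times (6-hourly, synoptic hours).
#' @param levels Pressure levels, mb (subset of the standard layers).
#' @return A [wind_field()]; deterministic under a fixed `cfg$seed`.
#' @export
generate_synthetic_wind <- function(cfg, extent, times,
                                    levels = c(1000, 925, 850, 775)) {
  stopifnot(inherits(cfg, "synthetic_wind_config"))
  shear <- rep_len(cfg$shear_profile, length(levels))
  nt <- length(times); nl <- length(levels)
  nla <- length(extent$lats); nlo <- length(extent$lons)

  noise <- matrix(0, nt, 2L)
  if (cfg$temporal_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$seed)
    innov_sd <- cfg$temporal_sd * sqrt(1 - cfg$ar1^2)
    for (k in 1:2) {
      e <- stats::rnorm(nt, 0, innov_sd)
      z <- numeric(nt)
      z[1] <- stats::rnorm(1, 0, cfg$temporal_sd)
      for (i in seq_len(nt - 1L)) z[i + 1L] <- cfg$ar1 * z[i] + e[i + 1L]
      noise[, k] <- z
    }
  }
  mu_u <- cfg$mean_trade_u * cfg$seasonal_reversal
  mu_v <- cfg$mean_trade_v * cfg$seasonal_reversal
  u <- array(0, dim = c(nt, nl, nla, nlo))
  v <- array(0, dim = c(nt, nl, nla, nlo))
  for (li in seq_len(nl)) {
    u[, li, , ] <- rep(mu_u * shear[li] + noise[, 1L], times = nla * nlo)
    v[, li, , ] <- rep(mu_v * shear[li] + noise[, 2L], times = nla * nlo)
  }
  wind_field(times, levels, extent$lats, extent$lons, u, v)
}

# Save/restore the global RNG state so generators with their own seed do not
# perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Helper: 6-hourly synoptic times
#'
#' @param start `POSIXct` UTC or ISO string; snapped forward to the next
#'   synoptic hour if needed.
#' @param n Number of analysis times.
#' @return `POSIXct` vector of length `n` at 6-h spacing.
#' @export
synoptic_times <- function(start, n) {
  t0 <- as.POSIXct(start, tz = "UTC")
  secs <- as.numeric(t0)
  snapped <- ceiling(secs / 21600) * 21600
  as.POSIXct(snapped + 21600 * (seq_len(n) - 1L), tz = "UTC",
             origin = "1970-01-01")
}
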