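# Geodesy and flight mechanics: great-circle geometry, wind decomposition,
# drift-compensated groundspeed and edge travel times.

#' Earth radius used throughout (metres, spherical Earth)
#' @keywords internal
EARTH_RADIUS_M <- 6371000

#' Constant-airspeed flight policy
#'
#' The route simulation assumes flapping flight at a constant airspeed.
#' The default of 18.05 m/s is the airspeed measured for Black-tailed
#' Godwits in powered migratory flight.
#'
#' @param airspeed Airspeed in m/s; must be positive.
#' @return An object of class `airspeed_policy`.
#' @export
#' @examples
#' airspeed_policy()          # 18.05 m/s
#' airspeed_policy(15)
airspeed_policy <- function(airspeed = 18.05) {
  stopifnot(is.numeric(airspeed), length(airspeed) == 1L, is.finite(airspeed))
  if (airspeed <= 0) stop("airspeed must be > 0")
  structure(list(airspeed = airspeed), class = "airspeed_policy")
}

#' Great-circle distance and initial bearing
#'
#' Haversine distance on a sphere of radius 6 371 000 m and the initial
#' bearing of the great circle, clockwise from geographic north.
#' Identical points return distance 0 and, by convention, bearing 0.
#'
#' @param lat1,lon1 Origin in decimal degrees (vectorised).
#' @param lat2,lon2 Destination in decimal degrees (vectorised).
#' @return A list with numeric vectors `distance_m` and `bearing_deg`
#'   (bearing in `[0, 360)`).
#' @export
#' @examples
#' great_circle(0, 0, 0, 1)   # ~111.2 km due east
great_circle <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  d <- geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
  b <- geosphere::bearing(p1, p2) %% 360
  same <- d == 0
  b[same] <- 0
  list(distance_m = as.numeric(d), bearing_deg = as.numeric(b))
}

#' Tailwind and crosswind components along a track
#'
#' Projects the horizontal wind vector (u eastward, v northward) onto the
#' direction of travel. This is a pure rotation:
#' `tailwind^2 + crosswind^2 = u^2 + v^2`.
#'
#' @param u,v Wind components in m/s (vectorised).
#' @param track_bearing_deg Track direction, degrees clockwise from north.
#' @return A list with numeric vectors `tailwind` and `crosswind` (m/s).
#'   Positive crosswind blows from left to right across the track.
#' @export
#' @examples
#' wind_components(0, 10, 0)    # pure tailwind when flying north
wind_components <- function(u, v, track_bearing_deg) {
  th <- track_bearing_deg * pi / 180
  list(tailwind = u * sin(th) + v * cos(th),
       crosswind = u * cos(th) - v * sin(th))
}

#' Drift-compensated groundspeed
#'
#' The bird holds a heading such that its track over ground equals the
#' intended bearing; the crosswind is offset by a heading correction and
#' the along-track speed is `tailwind + sqrt(airspeed^2 - crosswind^2)`.
#' A leg is infeasible (returned as `NA`) when `|crosswind| >= airspeed`
#' (the crosswind cannot be compensated) or when the resulting groundspeed
#' is not positive (no net progress against the headwind).
#'
#' @param tailwind,crosswind Wind components along/across track, m/s
#'   (vectorised).
#' @param policy An [airspeed_policy()].
#' @return Numeric vector of groundspeeds (m/s), `NA` where infeasible.
#' @export
groundspeed <- function(tailwind, crosswind, policy = airspeed_policy()) {
  a <- policy$airspeed
  g <- ifelse(abs(crosswind) >= a, NA_real_,
              tailwind + sqrt(pmax(a^2 - crosswind^2, 0)))
  g[!is.na(g) & g <= 0] <- NA_real_
  g
}

#' Travel time between two nodes under a given wind
#'
#' The edge weight of the route graph: great-circle distance divided by the
#' drift-compensated groundspeed along the leg's initial bearing, using the
#' wind matched to the origin node. Infeasible legs get weight `Inf` so
#' that path search degrades gracefully rather than failing.
#'
#' @param lat1,lon1,lat2,lon2 Leg endpoints, decimal degrees (vectorised).
#' @param u,v Wind at the origin node, m/s.
#' @param policy An [airspeed_policy()].
#' @return Numeric vector of travel times in seconds (`Inf` = infeasible).
#'   Purely vertical pairs (identical lat/lon) are rejected with an error:
#'   a zero-length edge would have zero cost and make altitude changes free.
#' @export
#' @examples
#' edge_travel_time(0, 0, 0, 1, u = 0, v = 0)  # still air: d / 18.05
edge_travel_time <- function(lat1, lon1, lat2, lon2, u, v,
                             policy = airspeed_policy()) {
  gc <- great_circle(lat1, lon1, lat2, lon2)
  if (any(gc$distance_m == 0)) {
    stop("purely vertical (zero horizontal distance) edges are not allowed")
  }
  wc <- wind_components(u, v, gc$bearing_deg)
  g <- groundspeed(wc$tailwind, wc$crosswind, policy)
  t <- gc$distance_m / g
  t[is.na(t)] <- Inf
  t
}
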