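# Synthetic stand-ins for the study's inputs: trade-wind fields, a
# desk-scale migratory corridor, duty-cycled Argos-style tracks and fates
# with known generating parameters, so every pipeline stage has a recovery
# target.

#' Desk-scale synthetic migratory corridor and desert mask
#'
#' A narrow north-south corridor (the synthetic stand-in for the godwit
#' migratory zone between Iberia and the Sahel) and the desert band that
#' defines a crossing. Purely synthetic geometry: the real corridor spans
#' West Africa to Iberia; this one is sized so that grids stay small while
#' preserving the structure (non-stop transit of a barrier band flanked by
#' staging areas).
#'
#' @return A list with `corridor` and `mask` polygons (data frames `lat`,
#'   `lon`), the staging latitude band (`north_lat`, `south_lat`), a
#'   nominal `lon` range for sites, and default `levels`.
#' @export
synthetic_geography <- function() {
  list(corridor = data.frame(lat = c(11, 11, 27, 27), lon = c(-8, -4, -4, -8)),
       mask = data.frame(lat = c(15, 15, 23, 23), lon = c(-9, -3, -3, -9)),
       south_lat = c(11.6, 12.8), north_lat = c(24.8, 26.0),
       site_lon = c(-6.8, -5.2),
       levels = c(1000, 925, 850, 775))
}

#' Paired seasonal wind fields
#'
#' Generates the southward-season and northward-season wind fields for the
#' synthetic study: the same prevailing north-easterly trades in both
#' (optionally scaled by `cfg$seasonal_reversal` for the northward field),
#' so that the flow aids south-westward flight and opposes north-eastward
#' flight — the qualitative contrast the pipeline must detect.
#'
#' @param cfg A [synthetic_wind_config()]; its `seed` controls both fields
#'   (the northward field uses `seed + 1`).
#' @param n_times Analysis times per field (6-hourly; default 56 = 14 d).
#' @param start_south,start_north UTC start of each seasonal window.
#' @param geo A [synthetic_geography()] list.
#' @return A list with `wind_field`s `southward` and `northward`.
#' @export
generate_seasonal_scenario <- function(cfg = synthetic_wind_config(),
                                       n_times = 56,
                                       start_south = "2017-06-10 00:00:00",
                                       start_north = "2018-04-05 00:00:00",
                                       geo = synthetic_geography()) {
  extent <- list(lats = seq(min(geo$corridor$lat), max(geo$corridor$lat), by = 0.8),
                 lons = seq(min(geo$corridor$lon), max(geo$corridor$lon), by = 0.8))
  cfg_n <- cfg
  cfg_n$seed <- cfg$seed + 1L
  list(southward = generate_synthetic_wind(cfg, extent,
                                           synoptic_times(start_south, n_times),
                                           geo$levels),
       northward = generate_synthetic_wind(cfg_n, extent,
                                           synoptic_times(start_north, n_times),
                                           geo$levels))
}

#' Cohort generator configuration
#'
#' Defaults mirror the study population: 53 tagged adults followed over up
#' to two seasons per year, 9.5 g transmitters on a 8 h on / 24 h charge
#' (32 birds) or 10 h on / 48 h charge (15 birds) duty cycle, 5 g tags
#' (4 birds) all on 8/24; 7 +/- 2 retained fixes per crossing; in-flight
#' mortality on the northward crossing with
#' `logit(P(die)) = intercept + slope * flight_time_h` (defaults -10 and
#' 0.25/h, which give ~25% mortality at a 35 h crossing).
#'
#' @param n_individuals Number of birds.
#' @param seasons Seasons simulated per individual.
#' @param fix_mean,fix_sd Target in-flight fix count (mean, SD).
#' @param prop_tag_5g Fraction of birds with a 5 g transmitter.
#' @param prop_duty_1048 Fraction of 9.5 g birds on the 10/48 duty cycle.
#' @param mortality_intercept,mortality_slope Logit-scale mortality model
#'   (northward crossings only; no southward deaths were observed).
#' @param jitter_sd_deg Gaussian cross-track noise of the flown trajectory
#'   relative to the great circle, degrees.
#' @param seed RNG seed; a fixed seed yields a byte-identical cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 60,
                          seasons = c("southward", "northward"),
                          fix_mean = 7, fix_sd = 2,
                          prop_tag_5g = 4 / 53,
                          prop_duty_1048 = 15 / 47,
                          mortality_intercept = -10,
                          mortality_slope = 0.25,
                          jitter_sd_deg = 0.15,
                          seed = 1L) {
  stopifnot(prop_tag_5g >= 0, prop_tag_5g <= 1, fix_sd >= 0)
  structure(list(n_individuals = n_individuals, seasons = seasons,
                 fix_mean = fix_mean, fix_sd = fix_sd,
                 prop_tag_5g = prop_tag_5g, prop_duty_1048 = prop_duty_1048,
                 mortality_intercept = mortality_intercept,
                 mortality_slope = mortality_slope,
                 jitter_sd_deg = jitter_sd_deg, seed = as.integer(seed)),
            class = "cohort_config")
}

duty_cycle_spec <- function(code) {
  switch(code,
         "8/24" = c(on = 8, off = 24),
         "10/48" = c(on = 10, off = 48),
         stop("unknown duty cycle: ", code))
}

# Realized (truth-side) trajectory: fly the great circle from dep to arr at
# constant airspeed, at each step choosing the pressure level with the best
# groundspeed under the wind matched to the current clock time. Returns the
# time-parameterised track.
fly_track <- function(field, dep_lat, dep_lon, arr_lat, arr_lon, dep_time,
                      policy = airspeed_policy(), nsteps = 48L) {
  f <- seq(0, 1, length.out = nsteps + 1L)
  lat <- dep_lat + f * (arr_lat - dep_lat)
  lon <- dep_lon + f * (arr_lon - dep_lon)
  tsec <- numeric(nsteps + 1L)
  tsec[1] <- as.numeric(dep_time)
  lev <- integer(nsteps + 1L)
  nl <- length(field$levels)
  for (i in seq_len(nsteps)) {
    gcs <- great_circle(lat[i], lon[i], lat[i + 1], lon[i + 1])
    wl <- sample_wind(field,
                      rep(lat[i], nl), rep(lon[i], nl), field$levels,
                      as.POSIXct(rep(tsec[i], nl), tz = "UTC",
                                 origin = "1970-01-01"))
    wc <- wind_components(wl$u, wl$v, gcs$bearing_deg)
    g <- groundspeed(wc$tailwind, wc$crosswind, policy)
    if (all(is.na(g))) g <- rep(1, nl)  # slog on at minimal progress
    li <- which.max(ifelse(is.na(g), -Inf, g))
    lev[i] <- li
    tsec[i + 1L] <- tsec[i] + gcs$distance_m / max(g[li], 1, na.rm = TRUE)
  }
  lev[nsteps + 1L] <- lev[nsteps]
  data.frame(lat = lat, lon = lon, tsec = tsec, level = field$levels[lev])
}

track_position <- function(track, tsec) {
  lat <- stats::approx(track$tsec, track$lat, xout = tsec, rule = 2)$y
  lon <- stats::approx(track$tsec, track$lon, xout = tsec, rule = 2)$y
  data.frame(lat = lat, lon = lon)
}

duty_on <- function(tsec, phase_sec, spec) {
  period <- (spec["on"] + spec["off"]) * 3600
  ((tsec - phase_sec) %% period) < spec["on"] * 3600
}

argos_lc <- function(n, with_z = TRUE) {
  if (with_z) {
    sample(c("3", "2", "1", "0", "A", "B", "Z"), n, replace = TRUE,
           prob = c(0.10, 0.15, 0.20, 0.25, 0.15, 0.13, 0.02))
  } else {
    sample(c("3", "2", "1", "0", "A", "B"), n, replace = TRUE,
           prob = c(0.10, 0.15, 0.20, 0.25, 0.15, 0.15))
  }
}

sensor_values <- function(n, tag, mode, tsec) {
  # mode: "alive", "dead_activity" (constant activity), "dead_temperature"
  # (carcass follows the ambient diurnal cycle)
  if (tag == "9.5g") {
    act <- if (mode == "dead_activity") rep(42, n) else round(stats::runif(n, 0, 255))
    data.frame(activity = act, temperature = NA_real_)
  } else {
    tmp <- if (mode == "dead_temperature") {
      h <- tsec / 3600
      25 + 8 * sin(2 * pi * (h - 10) / 24) + stats::rnorm(n, 0, 0.3)
    } else {
      40 + stats::rnorm(n, 0, 0.3)  # regulated body temperature
    }
    data.frame(activity = NA_real_, temperature = tmp)
  }
}

#' Generate a complete synthetic cohort
#'
#' For each individual and season, a trajectory is flown through the wind
#' field (great circle plus Gaussian cross-track jitter, constant 18.05
#' m/s airspeed, level chosen greedily for groundspeed), subsampled by the
#' transmitter duty cycle; fate is drawn from the logistic mortality model
#' applied to the truth-side realized flight time; dead birds' fixes are
#' truncated at a uniform fraction of the crossing and their sensor
#' channels altered according to the generating death rule (constant
#' activity, diurnal temperature, or transmission cessation). The truth
#' table records every generating parameter.
#'
#' @param cfg A [cohort_config()].
#' @param fields Named list of [wind_field()]s by season (e.g. from
#'   [generate_seasonal_scenario()]); a single field is recycled.
#' @param geo A [synthetic_geography()] list; the fields must cover it.
#' @return A list with `fixes` (Argos-style fix table: `id`, `timestamp`,
#'   `lat`, `lon`, `lc`, `activity`, `temperature`, `tag_type`,
#'   `crossing_id`, `phase`), `truth` (one row per crossing) and `config`.
#' @export
generate_cohort <- function(cfg, fields, geo = synthetic_geography()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (inherits(fields, "wind_field")) {
    fields <- stats::setNames(rep(list(fields), length(cfg$seasons)), cfg$seasons)
  }
  for (s in cfg$seasons) {
    fl <- fields[[s]]
    if (is.null(fl)) stop("no wind field supplied for season ", s)
    if (min(fl$lats) > min(geo$corridor$lat) || max(fl$lats) < max(geo$corridor$lat) ||
        min(fl$lons) > min(geo$corridor$lon) || max(fl$lons) < max(geo$corridor$lon)) {
      stop("wind field does not cover the corridor")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  n <- cfg$n_individuals
  ind <- sprintf("G%03d", seq_len(n))
  tag <- ifelse(stats::runif(n) < cfg$prop_tag_5g, "5g", "9.5g")
  duty <- ifelse(tag == "5g", "8/24",
                 ifelse(stats::runif(n) < cfg$prop_duty_1048, "10/48", "8/24"))
  south_site <- data.frame(lat = stats::runif(n, geo$south_lat[1], geo$south_lat[2]),
                           lon = stats::runif(n, geo$site_lon[1], geo$site_lon[2]))
  north_site <- data.frame(lat = stats::runif(n, geo$north_lat[1], geo$north_lat[2]),
                           lon = stats::runif(n, geo$site_lon[1], geo$site_lon[2]))
  phase <- stats::runif(n, 0, 72 * 3600)  # duty-cycle phase per transmitter

  fixes <- list()
  truth <- list()
  policy <- airspeed_policy()
  for (i in seq_len(n)) {
    alive <- TRUE
    for (s in cfg$seasons) {
      if (!alive) break
      fld <- fields[[s]]
      if (s == "southward") {
        dep <- north_site[i, ]; arr <- south_site[i, ]
      } else {
        dep <- south_site[i, ]; arr <- north_site[i, ]
      }
      dep <- lapply(dep, snap_to_lattice)
      arr <- lapply(arr, snap_to_lattice)
      span <- as.numeric(max(fld$times)) - as.numeric(min(fld$times))
      dep_time <- as.POSIXct(as.numeric(min(fld$times)) +
                               stats::runif(1, 0.25, 0.6) * span,
                             tz = "UTC", origin = "1970-01-01")
      track <- fly_track(fld, dep$lat, dep$lon, arr$lat, arr$lon, dep_time,
                         policy)
      dur <- track$tsec[nrow(track)] - track$tsec[1]
      truth_h <- dur / 3600
      dsec0 <- track$tsec[1]
      mlo <- min(geo$mask$lat); mhi <- max(geo$mask$lat)
      mask_t <- range(track$tsec[track$lat >= mlo & track$lat <= mhi])

      died <- FALSE; rule <- "none"; death_frac <- NA_real_
      if (s == "northward") {
        p_die <- stats::plogis(cfg$mortality_intercept +
                                 cfg$mortality_slope * truth_h)
        died <- stats::runif(1) < p_die
        if (died) {
          # in-flight deaths happen over the desert itself: draw the death
          # time within the in-mask portion of the trajectory
          mspan <- diff(mask_t)
          death_sec <- stats::runif(1, mask_t[1] + 0.05 * mspan,
                                    mask_t[2] - 0.05 * mspan)
          death_frac <- (death_sec - dsec0) / dur
          rule <- if (tag[i] == "5g") {
            sample(c("temperature", "cessation"), 1, prob = c(0.7, 0.3))
          } else {
            sample(c("activity", "cessation"), 1, prob = c(0.7, 0.3))
          }
        }
      }
      cid <- paste(ind[i], s, format(dep_time, "%Y"), sep = "_")
      spec <- duty_cycle_spec(duty[i])

      emit <- function(tsec, lat, lon, mode, fphase, with_z = TRUE) {
        m <- length(tsec)
        if (m == 0L) return(NULL)
        sv <- sensor_values(m, tag[i], mode, tsec)
        data.frame(id = ind[i],
                   timestamp = as.POSIXct(tsec, tz = "UTC",
                                          origin = "1970-01-01"),
                   lat = lat, lon = lon, lc = argos_lc(m, with_z),
                   activity = sv$activity, temperature = sv$temperature,
                   tag_type = tag[i], crossing_id = cid, phase = fphase)
      }

      dsec <- as.numeric(dep_time)
      # pre-crossing: stationary at the departure site
      pre_t <- seq(dsec - 3 * 86400, dsec - 3600, by = 2 * 3600)
      pre_t <- pre_t[duty_on(pre_t, phase[i], spec)]
      pre <- emit(pre_t, dep$lat + stats::rnorm(length(pre_t), 0, 0.02),
                  dep$lon + stats::rnorm(length(pre_t), 0, 0.02),
                  "alive", "pre")

      # in-flight: duty-cycled subsample of the trajectory. Every documented
      # crossing in the emulated data product carries desert fixes, so the
      # duty phase is re-anchored per crossing (transmitter clocks drift
      # between seasons) to put a transmission window inside the mask, and
      # one in-mask fix is always retained.
      end_sec <- if (died) dsec + death_frac * dur else dsec + dur
      in_mask_t <- track$tsec[track$lat >= mlo & track$lat <= mhi]
      in_mask_t <- in_mask_t[in_mask_t > dsec & in_mask_t <= end_sec]
      phase_c <- if (length(in_mask_t) > 0L) {
        stats::runif(1, min(in_mask_t),
                     max(min(in_mask_t), max(in_mask_t) - spec["on"] * 1800))
      } else phase[i]
      cand <- seq(dsec + 900, end_sec, by = 1800)
      cand <- cand[duty_on(cand, phase_c, spec)]
      n_fix <- max(1L, round(stats::rnorm(1, cfg$fix_mean, cfg$fix_sd)))
      cand_lat <- track_position(track, cand)$lat
      in_mask <- cand_lat >= mlo & cand_lat <= mhi
      if (any(in_mask) && length(cand) > n_fix) {
        forced <- sample(cand[in_mask], 1)
        rest <- setdiff(cand, forced)
        cand <- sort(c(forced, sample(rest, n_fix - 1L)))
      } else if (length(cand) > n_fix) {
        cand <- sort(sample(cand, n_fix))
      }
      pos <- track_position(track, cand)
      infl <- emit(cand,
                   pos$lat + stats::rnorm(length(cand), 0, cfg$jitter_sd_deg),
                   pos$lon + stats::rnorm(length(cand), 0, cfg$jitter_sd_deg),
                   "alive", "crossing", with_z = FALSE)

      post <- NULL
      if (!died) {
        post_t <- seq(dsec + dur + 3600, dsec + dur + 16 * 86400, by = 2 * 3600)
        post_t <- post_t[duty_on(post_t, phase[i], spec)]
        post <- emit(post_t, arr$lat + stats::rnorm(length(post_t), 0, 0.02),
                     arr$lon + stats::rnorm(length(post_t), 0, 0.02),
                     "alive", "post")
      } else if (rule != "cessation") {
        dpos <- track_position(track, end_sec)
        post_t <- seq(end_sec + 3600, end_sec + 14 * 86400, by = 2 * 3600)
        post_t <- post_t[duty_on(post_t, phase[i], spec)]
        mode <- if (rule == "activity") "dead_activity" else "dead_temperature"
        post <- emit(post_t, rep(dpos$lat, length(post_t)),
                     rep(dpos$lon, length(post_t)), mode, "post")
      }

      fixes[[length(fixes) + 1L]] <- rbind(pre, infl, post)
      truth[[length(truth) + 1L]] <- data.frame(
        crossing_id = cid, individual = ind[i], season = s,
        tag_type = tag[i], duty_cycle = duty[i],
        dep_lat = dep$lat, dep_lon = dep$lon,
        dep_time = dep_time,
        arr_lat = arr$lat, arr_lon = arr$lon,
        arr_time = as.POSIXct(dsec + dur, tz = "UTC", origin = "1970-01-01"),
        truth_flight_time_h = truth_h,
        departure_doy = as.integer(format(dep_time, "%j", tz = "UTC")),
        died = died, death_rule = rule, death_frac = death_frac,
        n_inflight_fixes = if (is.null(infl)) 0L else nrow(infl))
      if (died) alive <- FALSE
    }
  }
  fixes <- do.call(rbind, fixes)
  fixes <- fixes[order(fixes$id, fixes$timestamp), ]
  rownames(fixes) <- NULL
  list(fixes = fixes, truth = do.call(rbind, truth), config = cfg)
}

#' Synthetic northward mortality cohort at the observed study scale
#'
#' Draws crossings with minimal flight times at the observed northward
#' distribution (default mean 35.18 h, SD 5.10 h) and fates from
#' `logit(P(die)) = intercept + slope * flight_time_h`, together with the
#' covariates entering the mortality model (relative departure date, tag
#' type, individual identity with an optional random-intercept SD).
#' Intended for parameter-recovery and calibration studies of
#' [fit_mortality_glmm()].
#'
#' @param n_crossings Number of northward crossings.
#' @param n_individuals Number of birds the crossings are spread over.
#' @param intercept,slope Generating logit-scale parameters.
#' @param time_mean,time_sd Flight-time distribution (hours).
#' @param doy_mean,doy_sd Departure day-of-year distribution.
#' @param prop_tag_5g Fraction of 5 g transmitters.
#' @param individual_sd SD of the individual random intercept (logit).
#' @param seed RNG seed.
#' @return Data frame with `individual`, `flight_time_h`,
#'   `relative_departure_days`, `tag_type`, `died`.
#' @export
generate_mortality_cohort <- function(n_crossings = 400, n_individuals = 200,
                                      intercept = -10, slope = 0.25,
                                      time_mean = 35.18, time_sd = 5.10,
                                      doy_mean = 105, doy_sd = 7,
                                      prop_tag_5g = 4 / 53,
                                      individual_sd = 0, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ind <- sample(sprintf("B%03d", seq_len(n_individuals)), n_crossings,
                replace = TRUE)
  re <- stats::setNames(stats::rnorm(n_individuals, 0, individual_sd),
                        sprintf("B%03d", seq_len(n_individuals)))
  ft <- stats::rnorm(n_crossings, time_mean, time_sd)
  doy <- round(stats::rnorm(n_crossings, doy_mean, doy_sd))
  tag <- ifelse(stats::runif(n_crossings) < prop_tag_5g, "5g", "9.5g")
  eta <- intercept + slope * ft + re[ind]
  died <- as.integer(stats::runif(n_crossings) < stats::plogis(eta))
  data.frame(individual = ind, flight_time_h = ft,
             relative_departure_days = relative_departure_date(doy, doy),
             tag_type = tag, died = died)
}
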