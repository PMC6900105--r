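# windcross

Wind-optimal route simulation and in-flight mortality analysis for birds
crossing large ecological barriers, built for satellite-telemetry studies
of trans-Saharan migrants (Black-tailed Godwits and species tracked with
similar duty-cycled Argos transmitters).

## What it does

Solar Argos transmitters deliver only ~7 fixes per desert crossing and no
altitude, so the wind assistance a bird experienced in flight cannot be
read off its track. `windcross` instead simulates the **minimal flight
time** of each crossing: the duration of the time-optimal route from the
observed departure node to the observed arrival node through a 3D grid of
candidate positions (0.4° lattice × pressure levels 1000–500 mb), with
edges weighted by travel time under the wind analysis matched to each
node. For a leg with bearing θ and wind (u, v),

    tailwind  = u·sin θ + v·cos θ
    crosswind = u·cos θ − v·sin θ
    groundspeed = tailwind + √(airspeed² − crosswind²),  airspeed = 18.05 m/s
    edge weight = great-circle distance / groundspeed

and the minimal flight time is the Dijkstra shortest path under these
weights. A crossing flown into adverse winds has a long minimal flight
time regardless of routing, so it serves as a proxy for wind-induced
flight cost. On top of this the package provides:

* **Track ingestion** — Argos location-class filtering (retain
  3/2/1/0/A/B), desert-crossing segmentation, and fate classification
  from transmitter diagnostics (constant activity sensor, onset of a
  diurnal temperature rhythm, or transmission cessation mid-bout);
* **Inference** — mixed models with individual random intercepts for the
  seasonal contrast in minimal flight time, for in-flight mortality
  (`died ~ flight_time + relative_departure_date + tag_type`), and for
  the informed-vs-uninformed robustness comparison, each tested by
  parametric bootstrap (simulate-from-null, refit, compare LRTs);
* **Synthetic data** — trade-wind fields, duty-cycled tracks and fates
  with known generating parameters, so every stage of the pipeline has a
  recovery target.

See the vignette `vignettes/wind-assisted-crossings.Rmd` for the model,
its assumptions and the design choices.

## Worked example

Simulate a northward crossing of a synthetic trade-wind corridor and fit
the seasonal contrast over a 60-bird cohort:

```r
library(windcross)

geo      <- synthetic_geography()
scenario <- generate_seasonal_scenario(synthetic_wind_config(seed = 1))

grid <- build_grid(geo$corridor, resolution = 0.4, levels = geo$levels)
grid
#> <node_grid> 1760 nodes (uninformed), 32180 directed edges, 4 levels, 0.4 deg

route <- minimal_flight_time(grid, scenario$northward,
  departure = list(lat = 12.4, lon = -6), arrival = list(lat = 25.2, lon = -6),
  departure_time = as.POSIXct("2018-04-08 06:00:00", tz = "UTC"))
route
#> <route_result> 30.01 h over 32 edges (uninformed grid), departing 2018-04-08 06:00:00 UTC
```

Flying the same corridor against the north-easterly trades takes 30 h
here versus ~18 h with them (run the southward field to see it). Cohort
level:

```r
cohort <- generate_cohort(cohort_config(n_individuals = 60, seed = 1),
                          scenario, geo)
tr <- cohort$truth
crossings <- data.frame(crossing_id = tr$crossing_id, individual = tr$individual,
  season = tr$season, dep_lat = tr$dep_lat, dep_lon = tr$dep_lon,
  dep_time = tr$dep_time, arr_lat = tr$arr_lat, arr_lon = tr$arr_lon)
routes <- simulate_routes(crossings, scenario, geo$corridor, geo$levels)

fit <- fit_season_lmm(data.frame(flight_time_h = routes$total_time_h,
                                 season = routes$season,
                                 individual = routes$individual),
                      B = 199, seed = 1)
fit
#> <windcross_fit> 120 obs, 60 individuals; random-intercept SD = 0
#>             term estimate        se boot_p
#>      (Intercept) 18.29579 0.3497918     NA
#>  seasonnorthward 11.16467 0.4946804  0.005
#> notes: singular fit (random-intercept variance at boundary)
```

The northward season costs ~11 h more minimal flight time than the
southward season in this scenario (bootstrap p = 0.005 at B = 199); the
intercept is the mean southward minimal flight time in hours. The
singular-fit note says the individual random-intercept variance was
estimated at zero — reported, not hidden.

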