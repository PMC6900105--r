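Package: windcross
Title: Wind-Optimal Route Simulation and In-Flight Mortality Analysis for
    Trans-Saharan Bird Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the wind assistance experienced by migratory
    birds crossing large ecological barriers. Simulates the minimal (wind
    optimal) flight time of a desert crossing by shortest-path search through
    a three-dimensional grid of candidate flight positions (latitude x
    longitude x pressure level) weighted by travel times under gridded
    reanalysis-style wind fields; ingests Argos-style satellite telemetry,
    classifies in-flight fates from transmitter diagnostics, and fits
    mixed-effects models relating minimal flight time and departure date to
    in-flight mortality, with parametric-bootstrap significance tests.
    Includes a synthetic-data generator (trade-wind fields, duty-cycled
    tracks, fates with known parameters) so every stage has a recovery
    target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    lme4,
    pracma,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
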