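make_track <- function(lats, t0 = "2017-04-10 00:00:00", step_h = 3,
                       id = "X1", lc = "3", lon = -6, tag = "9.5g") {
  n <- length(lats)
  data.frame(id = id,
             timestamp = utc(t0) + (seq_len(n) - 1) * step_h * 3600,
             lat = lats, lon = lon, lc = lc,
             activity = round(runif(n, 0, 255)), temperature = NA_real_,
             tag_type = tag)
}

desert_band <- function() box_corridor(15, 23, -9, -3)

test_that("quality filter retains 3/2/1/0/A/B, drops Z, and is idempotent", {
  fx <- data.frame(lc = c("3", "B", "Z", "A"), x = 1:4)
  out <- quality_filter(fx)
  expect_equal(out$lc, c("3", "B", "A"))
  expect_equal(out$x, c(1, 2, 4))                  # order preserved

  expect_equal(nrow(quality_filter(data.frame(lc = rep("Z", 5)))), 0)
  expect_identical(quality_filter(out), out)       # idempotent
  expect_warning(quality_filter(data.frame(lc = "Q")), "unknown location class")
})

test_that("crossing segmentation finds desert transits and assigns season", {
  set.seed(1)
  # northbound: 2 fixes south of the band, 7 inside, 2 north of it
  tr <- make_track(c(13, 14.3, seq(15.4, 22.6, length.out = 7), 23.8, 25))
  crs <- segment_crossing(tr, desert_band())
  expect_length(crs, 1)
  expect_equal(nrow(crs[[1]]$fixes), 7)
  expect_equal(crs[[1]]$season, "northward")
  expect_true(crs[[1]]$complete)
  expect_equal(crs[[1]]$dep_lat, 14.4)             # snapped to 0.4 lattice
  expect_false(crs[[1]]$low_confidence)

  # southbound direction is detected from the net latitude change
  tr_s <- make_track(rev(c(13, 14.2, seq(15.4, 22.6, length.out = 7), 23.8, 25)))
  expect_equal(segment_crossing(tr_s, desert_band())[[1]]$season, "southward")

  # a track that never enters the mask yields no crossing
  expect_length(segment_crossing(make_track(c(24, 25, 26)), desert_band()), 0)
})

test_that("a duty-cycle gap spanning desert entry flags the crossing low-confidence", {
  tr <- make_track(c(13, 14.2, seq(17, 22.6, length.out = 5), 23.8, 25))
  # 30-h gap between the last pre-desert fix and the first in-desert fix
  tr$timestamp[3:nrow(tr)] <- tr$timestamp[3:nrow(tr)] + 30 * 3600
  crs <- segment_crossing(tr, desert_band())
  expect_length(crs, 1)
  expect_true(crs[[1]]$low_confidence)
})

test_that("relative departure date is the offset from the reference mean", {
  expect_equal(relative_departure_date(104, c(100, 102, 104)), 2)
  expect_equal(relative_departure_date(102, c(100, 102, 104)), 0)
  expect_equal(relative_departure_date(100, 100), 0)   # single-crossing reference
  expect_error(relative_departure_date(100, numeric(0)), "empty reference")
})

test_that("fate diagnostics fire on their designed signatures", {
  set.seed(7)
  band <- desert_band()

  # rule 1: 9.5 g, activity constant after a mid-desert stop
  alive <- make_track(c(13, 14.2, 16, 18, 19.5))
  t_end <- max(alive$timestamp)
  dead_fix <- data.frame(id = "X1",
                         timestamp = t_end + seq(3600, 10 * 86400, by = 7200),
                         lat = 19.5, lon = -6, lc = "B",
                         activity = 42, temperature = NA_real_,
                         tag_type = "9.5g")
  all_fx <- rbind(alive, dead_fix)
  cr <- segment_crossing(all_fx, band)[[1]]
  fate <- classify_fate(cr, all_fx)
  expect_equal(as.character(fate), "died")
  expect_equal(attr(fate, "rule"), "activity")

  # rule 2: 5 g, temperature flat in life then strongly diurnal
  alive5 <- make_track(c(13, 14.2, 16, 18, 19.5), tag = "5g")
  alive5$activity <- NA_real_
  alive5$temperature <- 40 + rnorm(nrow(alive5), 0, 0.3)
  post_t <- t_end + seq(3600, 10 * 86400, by = 7200)
  h <- as.numeric(post_t) / 3600
  dead5 <- data.frame(id = "X1", timestamp = post_t, lat = 19.5, lon = -6,
                      lc = "B", activity = NA_real_,
                      temperature = 25 + 8 * sin(2 * pi * h / 24) +
                        rnorm(length(post_t), 0, 0.3),
                      tag_type = "5g")
  all5 <- rbind(alive5, dead5)
  cr5 <- segment_crossing(all5, band)[[1]]
  fate5 <- classify_fate(cr5, all5)
  expect_equal(as.character(fate5), "died")
  expect_equal(attr(fate5, "rule"), "temperature")

  # rule 3: transmitter goes silent mid-crossing and never turns on again
  cr3 <- segment_crossing(alive, band)[[1]]
  fate3 <- classify_fate(cr3, alive)
  expect_equal(as.character(fate3), "died")
  expect_equal(attr(fate3, "rule"), "cessation")

  # ... but a later resighting overrides the rule, with a warning
  expect_warning(fate_rs <- classify_fate(cr3, alive, resighted = TRUE),
                 "resighted")
  expect_equal(as.character(fate_rs), "survived")

  # completed crossing with continuing transmissions: survived
  full <- make_track(c(13, 14.2, seq(15.4, 22.6, length.out = 7), 23.8, 25,
                       25, 25, 25, 25))
  cr_ok <- segment_crossing(full, band)[[1]]
  fate_ok <- classify_fate(cr_ok, full)
  expect_equal(as.character(fate_ok), "survived")
  expect_true(is.na(attr(fate_ok, "rule")))
})

test_that("fix tables round-trip through CSV with ISO-8601 timestamps", {
  tr <- make_track(c(13, 16, 19))
  p <- tempfile(fileext = ".csv")
  tr_out <- tr
  tr_out$timestamp <- format(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(tr_out, p, row.names = FALSE)
  back <- read_fixes(p)
  expect_equal(as.numeric(back$timestamp), as.numeric(tr$timestamp))
  expect_equal(back$lc, tr$lc)
  unlink(p)
})
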