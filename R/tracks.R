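# Argos-style track ingestion: quality-class retention, desert-crossing
# segmentation, in-flight fate classification and the relative departure
# date covariate.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")
RETAINED_CLASSES <- c("3", "2", "1", "0", "A", "B")

#' Read a fix table from CSV
#'
#' Expected columns: `id`, `timestamp` (ISO-8601 UTC), `lat`, `lon`,
#' `lc` (Argos location class), `activity`, `temperature`, `tag_type`
#' (`"5g"` or `"9.5g"`), one row per fix. Tracks are assumed to have been
#' pre-filtered with a plausibility filter upstream; only the class
#' retention rule is applied here (by [quality_filter()], not on read).
#'
#' @param path CSV path.
#' @return Data frame with `timestamp` parsed to `POSIXct` UTC, ordered by
#'   individual then time.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lc = "character"))
  need <- c("id", "timestamp", "lat", "lon", "lc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fix table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$timestamp <- parse_utc(df$timestamp)
  if (anyNA(df$timestamp)) stop("unparseable timestamps in fix table")
  df <- df[order(df$id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Retain fixes by Argos location class
#'
#' Keeps classes 3, 2, 1, 0, A and B; drops Z and anything unlisted.
#' Order-preserving and idempotent.
#'
#' @param fixes Data frame with a character `lc` column.
#' @return The filtered data frame.
#' @export
#' @examples
#' quality_filter(data.frame(lc = c("3", "B", "Z", "A")))
quality_filter <- function(fixes) {
  bad <- !(fixes$lc %in% ARGOS_CLASSES)
  if (any(bad)) {
    warning("dropping ", sum(bad), " fix(es) with unknown location class")
  }
  out <- fixes[fixes$lc %in% RETAINED_CLASSES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment a track into desert crossings
#'
#' A crossing is a maximal run of fixes inside the desert mask polygon.
#' The departure is the last fix before entry (snapped to the route
#' lattice) and the arrival the first fix after exit; a crossing whose
#' track never exits the mask again is incomplete (no arrival observed).
#' Season is assigned from the sign of the net latitude change.
#'
#' @param fixes One individual's fixes (quality-filtered, time-ordered):
#'   columns `id`, `timestamp`, `lat`, `lon`, optionally `tag_type`.
#' @param mask Desert mask polygon, data frame `lat`, `lon`.
#' @param resolution Lattice spacing used to snap departure/arrival nodes.
#' @param gap_hours Duty-cycle gap threshold: if the time from the
#'   departure fix to the first in-desert fix exceeds this, the crossing is
#'   flagged low-confidence.
#' @return A list of `crossing` objects (possibly empty), each with
#'   `individual`, `season`, `tag_type`, `dep_lat`, `dep_lon`, `dep_time`,
#'   `arr_lat`, `arr_lon`, `arr_time`, `complete`, `low_confidence` and
#'   `fixes` (the in-flight rows).
#' @export
segment_crossing <- function(fixes, mask, resolution = 0.4, gap_hours = 24) {
  stopifnot(nrow(fixes) >= 1)
  if (is.unsorted(fixes$timestamp)) fixes <- fixes[order(fixes$timestamp), ]
  inside <- pracma::inpolygon(fixes$lon, fixes$lat, mask$lon, mask$lat,
                              boundary = TRUE)
  if (!any(inside)) return(list())
  # despike: a single outside fix flanked by in-desert fixes does not end
  # a crossing (Argos scatter can momentarily jump across the mask edge)
  n <- length(inside)
  if (n >= 3L) {
    lone <- which(!inside[2:(n - 1L)] & inside[1:(n - 2L)] & inside[3:n]) + 1L
    inside[lone] <- TRUE
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L) next  # track starts inside the mask: no departure fix
    dep <- fixes[i0 - 1L, ]
    complete <- i1 < nrow(fixes)
    arr <- if (complete) fixes[i1 + 1L, ] else fixes[i1, ]
    infl <- fixes[i0:i1, , drop = FALSE]
    net_dlat <- arr$lat - dep$lat
    season <- if (net_dlat < 0) "southward" else "northward"
    low_conf <- as.numeric(difftime(infl$timestamp[1], dep$timestamp,
                                    units = "hours")) > gap_hours
    out[[length(out) + 1L]] <- structure(list(
      individual = dep$id,
      season = season,
      tag_type = if (!is.null(dep$tag_type)) dep$tag_type else NA_character_,
      dep_lat = snap_to_lattice(dep$lat, resolution),
      dep_lon = snap_to_lattice(dep$lon, resolution),
      dep_time = dep$timestamp,
      arr_lat = if (complete) snap_to_lattice(arr$lat, resolution) else NA_real_,
      arr_lon = if (complete) snap_to_lattice(arr$lon, resolution) else NA_real_,
      arr_time = if (complete) arr$timestamp else as.POSIXct(NA),
      complete = complete,
      low_confidence = low_conf,
      fixes = infl), class = "crossing")
  }
  out
}

#' Tuning constants for the fate diagnostics
#'
#' @param activity_var_ratio A 9.5 g bird is diagnosed dead when the sample
#'   variance of its activity channel over the post-event window falls
#'   below this fraction of its lifetime variance.
#' @param diurnal_amp_ratio A 5 g bird is diagnosed dead when the amplitude
#'   of the 24-h harmonic of its temperature channel exceeds this multiple
#'   of the residual SD over the post-event window.
#' @param window_days Length of the post-event diagnostic window.
#' @param silence_days A transmitter that stops mid-bout is "never on
#'   again" if it stays silent for at least this many days.
#' @param min_fixes Minimum post-event fixes needed to run rules 1-2.
#' @param min_span_days Minimum time span of the diagnostic window for
#'   rules 1-2; a 24-h harmonic fitted to fixes spanning less than a full
#'   day is unidentifiable, so short windows fall through to rule 3.
#' @return A list of parameters.
#' @export
fate_params <- function(activity_var_ratio = 1e-6, diurnal_amp_ratio = 3,
                        window_days = 7, silence_days = 365, min_fixes = 6,
                        min_span_days = 2) {
  list(activity_var_ratio = activity_var_ratio,
       diurnal_amp_ratio = diurnal_amp_ratio,
       window_days = window_days, silence_days = silence_days,
       min_fixes = min_fixes, min_span_days = min_span_days)
}

diurnal_amplitude_ratio <- function(timestamp, temperature) {
  h <- as.numeric(timestamp) / 3600
  X <- cbind(sin(2 * pi * h / 24), cos(2 * pi * h / 24))
  fit <- stats::lm.fit(cbind(1, X), temperature)
  amp <- sqrt(sum(fit$coefficients[2:3]^2))
  rsd <- stats::sd(fit$residuals)
  if (!is.finite(rsd) || rsd < 1e-9) rsd <- 1e-9
  amp / rsd
}

#' Classify the fate of a crossing from transmitter diagnostics
#'
#' Applies the three diagnostic rules: (1) a 9.5 g tag whose activity
#' sensor remains constant; (2) a 5 g tag whose temperature sensor starts
#' to follow a diurnal rhythm (the carcass tracks ambient temperature);
#' (3) a transmitter that stops transmitting within a migratory bout and
#' never turns on again, with no later resighting.
#'
#' For a crossing that was never completed, rules 1-2 are evaluated on the
#' final `window_days` of transmissions (a dead bird's tag keeps
#' transmitting from the carcass for a while, so the diagnostic signal
#' lives at the end of the record); for a completed crossing they are
#' evaluated on the window just after arrival. The activity baseline is
#' the lifetime variance over all earlier fixes. A later resighting always
#' overrides a fired rule (the bird is alive; a warning reports the
#' contradiction). A completed crossing with continuing transmissions or a
#' resighting is `survived`; anything else is `unknown`.
#'
#' @param crossing A `crossing` from [segment_crossing()].
#' @param all_fixes All fixes of the individual (including sensor columns
#'   `activity` and/or `temperature`), used to find post-event
#'   transmissions.
#' @param resighted Logical: was the bird resighted after the crossing?
#' @param params A [fate_params()] list.
#' @return Character scalar `"died"`, `"survived"` or `"unknown"`, with
#'   attribute `rule` (`"activity"`, `"temperature"`, `"cessation"` or
#'   `NA`) recording which diagnostic fired.
#' @export
classify_fate <- function(crossing, all_fixes, resighted = FALSE,
                          params = fate_params()) {
  stopifnot(inherits(crossing, "crossing"))
  tag <- crossing$tag_type
  if (is.na(tag)) stop("transmitter type must be known to classify fate")
  t_start <- min(crossing$fixes$timestamp)
  rel <- all_fixes[all_fixes$timestamp >= t_start, , drop = FALSE]
  last_tx <- max(rel$timestamp)
  if (crossing$complete) {
    win_start <- crossing$arr_time
    win_end <- win_start + params$window_days * 86400
  } else {
    win_end <- last_tx
    win_start <- win_end - params$window_days * 86400
  }
  win <- rel[rel$timestamp > win_start & rel$timestamp <= win_end, ,
             drop = FALSE]

  span_ok <- nrow(win) >= 2L &&
    diff(range(as.numeric(win$timestamp))) >= params$min_span_days * 86400

  rule <- NA_character_
  if (span_ok && tag == "9.5g" && !is.null(win$activity) &&
      sum(!is.na(win$activity)) >= params$min_fixes) {
    life_var <- stats::var(all_fixes$activity[all_fixes$timestamp <= win_start],
                           na.rm = TRUE)
    if (is.finite(life_var) && life_var > 0) {
      wv <- stats::var(win$activity, na.rm = TRUE)
      if (wv < params$activity_var_ratio * life_var) rule <- "activity"
    }
  }
  if (is.na(rule) && span_ok && tag == "5g" && !is.null(win$temperature) &&
      sum(!is.na(win$temperature)) >= params$min_fixes) {
    ratio <- diurnal_amplitude_ratio(win$timestamp, win$temperature)
    if (ratio > params$diurnal_amp_ratio) rule <- "temperature"
  }
  if (is.na(rule)) {
    silent_until <- last_tx + params$silence_days * 86400
    later <- all_fixes$timestamp > last_tx & all_fixes$timestamp <= silent_until
    never_again <- !any(later)
    mid_bout <- !crossing$complete
    if (mid_bout && never_again) rule <- "cessation"
  }

  if (!is.na(rule) && resighted) {
    warning("fate rule '", rule, "' fired but the bird was later resighted; ",
            "classifying as survived")
    out <- "survived"
    attr(out, "rule") <- NA_character_
    return(out)
  }
  if (!is.na(rule)) {
    out <- "died"
    attr(out, "rule") <- rule
    return(out)
  }
  continuing <- any(all_fixes$timestamp > crossing$arr_time)
  survived <- crossing$complete && (isTRUE(continuing) || resighted)
  out <- if (survived) "survived" else "unknown"
  attr(out, "rule") <- NA_character_
  out
}

#' Relative departure date
#'
#' Difference (days) between an individual departure day-of-year and the
#' grand mean departure day-of-year over all reference crossings for the
#' same season (the paper's reference is all northward departures from
#' Africa, 2014-2018).
#'
#' @param doy Numeric vector of departure days-of-year to score (1-based).
#' @param reference_doy Days-of-year of the reference crossing set.
#' @return `doy - mean(reference_doy)`, in days.
#' @export
#' @examples
#' relative_departure_date(104, c(100, 102, 104))   # +2
relative_departure_date <- function(doy, reference_doy) {
  if (length(reference_doy) == 0L || all(is.na(reference_doy))) {
    stop("empty reference set of departure dates")
  }
  doy - mean(reference_doy, na.rm = TRUE)
}
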