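# Biological seasons from lake temperature. Seasons are thermal states, not
# civil-calendar quarters: winter below the spring-onset threshold, spring
# from there until summer onset, summer until the surface cools past the fall
# threshold, fall until it drops back below the spring-onset threshold.

#' Analysis thresholds and fixed constants
#'
#' One home for every fixed constant used across the pipeline, with the
#' field-standard defaults: season thresholds 8/17/15 degC on a 7-day rolling
#' average of near-surface temperature; 500-mm maturity cutoff; depth days
#' need more than 20 depth detections and are summarized from a 20-value
#' subsample; COAs at 1-h intervals on a 1-km hex grid; model selection keeps
#' the most parsimonious fit within 2 AIC units; alpha 0.05.
#'
#' @param spring_onset_c,summer_onset_c,fall_onset_c season thresholds (degC).
#' @param rolling_days rolling-average window (days, odd).
#' @param maturity_cutoff_mm length at maturity (mm).
#' @param depth_day_min_detections minimum depth detections (exclusive) for an
#'   eligible depth day.
#' @param depth_subsample_size depth values drawn per eligible day.
#' @param coa_interval_h COA binning interval (hours).
#' @param hex_spacing_km hex-grid centroid spacing (km).
#' @param aic_window AIC parsimony window.
#' @param alpha significance level.
#' @return a `thresholds_config` list.
#' @export
thresholds_config <- function(spring_onset_c = 8, summer_onset_c = 17,
                              fall_onset_c = 15, rolling_days = 7,
                              maturity_cutoff_mm = 500,
                              depth_day_min_detections = 20,
                              depth_subsample_size = 20,
                              coa_interval_h = 1, hex_spacing_km = 1,
                              aic_window = 2, alpha = 0.05) {
  stopifnot(summer_onset_c > spring_onset_c, spring_onset_c > 0,
            rolling_days >= 1, rolling_days %% 2 == 1)
  structure(as.list(environment()), class = "thresholds_config")
}

#' Daily temperature experienced by sensor-tagged fish
#'
#' For each date, the coldest temperature recorded by each sensor-tagged fish
#' that day is taken, and those per-fish minima are averaged across fish.
#' Minima (not means) are used to capture the coldest habitat available to
#' the fish below the thermocline.
#'
#' @param detections detection data.frame with `tag`, `timestamp`,
#'   `temperature` (NA for non-sensor tags).
#' @return data.frame `date`, `temperature` (role attribute "experienced"),
#'   one row per date with at least one reading.
#' @export
daily_experienced <- function(detections) {
  ok <- !is.na(detections$temperature)
  if (!any(ok)) stop("no sensor temperature data", call. = FALSE)
  d <- detections[ok, ]
  d$date <- as.Date(d$timestamp, tz = "UTC")
  mins <- aggregate(temperature ~ tag + date, data = d, FUN = min)
  out <- aggregate(temperature ~ date, data = mins, FUN = mean)
  out <- out[order(out$date), c("date", "temperature")]
  rownames(out) <- NULL
  attr(out, "role") <- "experienced"
  out
}

#' Centred rolling mean of a daily series
#'
#' Window must be odd; at the edges the mean shrinks to the available days so
#' output dates equal input dates.
#'
#' @param series data.frame `date`, `temperature`, dates strictly increasing.
#' @param window window width in days (odd, >= 1).
#' @return data.frame of the same shape, smoothed.
#' @export
smooth_series <- function(series, window = 7) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (is.unsorted(series$date, strictly = TRUE))
    stop("series dates must be strictly increasing", call. = FALSE)
  n <- nrow(series)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, series$temperature))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  series$temperature <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  series
}

#' Classify biological seasons from smoothed surface temperature
#'
#' Deterministic daily state machine with hard transitions:
#' winter -> spring when T >= spring onset (8 degC; the printed spring range
#' "8-17" puts 8 in spring); spring -> summer when T > summer onset (17);
#' summer -> fall when T < fall onset (15); fall -> winter when T < spring
#' onset (8). A spring that cools below 8 without ever reaching 17 closes
#' directly as winter (no-summer year, with a warning).
#'
#' @param series smoothed surface series (`date`, `temperature`); should start
#'   in a winter-temperature period.
#' @param thresholds a [thresholds_config()].
#' @return a `season_calendar`: data.frame `start`, `end`, `label`, `year`
#'   with half-open day intervals `[start, end)` that partition the series
#'   range; `year` is the year of the interval start. Threshold values are
#'   attached as an attribute.
#' @export
classify_seasons <- function(series, thresholds = thresholds_config()) {
  th <- thresholds
  tv <- series$temperature
  n <- length(tv)
  if (n < 2L) stop("series too short", call. = FALSE)
  state <- character(n)
  s <- "winter"
  saw_summer <- FALSE
  for (i in seq_len(n)) {
    s <- switch(s,
      winter = if (tv[i] >= th$spring_onset_c) "spring" else "winter",
      spring = if (tv[i] > th$summer_onset_c) "summer"
               else if (tv[i] < th$spring_onset_c) "winter" else "spring",
      summer = if (tv[i] < th$fall_onset_c) "fall" else "summer",
      fall   = if (tv[i] < th$spring_onset_c) "winter" else "fall")
    if (s == "summer") saw_summer <- TRUE
    state[i] <- s
  }
  if (!saw_summer && any(tv >= th$spring_onset_c))
    warning("series never exceeded the summer-onset threshold: ",
            "calendar has no summer")
  brk <- c(1L, which(state[-1L] != state[-n]) + 1L)
  starts <- series$date[brk]
  ends <- c(series$date[brk[-1L]], series$date[n] + 1L)
  cal <- data.frame(start = starts, end = ends, label = state[brk],
                    year = as.integer(format(starts, "%Y")),
                    stringsAsFactors = FALSE)
  attr(cal, "thresholds") <- c(spring = th$spring_onset_c,
                               summer = th$summer_onset_c,
                               fall = th$fall_onset_c)
  class(cal) <- c("season_calendar", "data.frame")
  cal
}

#' Season membership of dates
#'
#' @param calendar a `season_calendar`.
#' @param dates Date (or POSIXct, converted in UTC) vector.
#' @return data.frame `label`, `year`, `instance` (label-year string) with NA
#'   for dates outside the calendar.
#' @export
season_at <- function(calendar, dates) {
  if (inherits(dates, "POSIXct")) dates <- as.Date(dates, tz = "UTC")
  i <- findInterval(as.numeric(dates), as.numeric(calendar$start))
  i[i == 0L] <- NA
  i[!is.na(i) & dates >= calendar$end[pmax(i, 1L)]] <- NA
  data.frame(label = calendar$label[i], year = calendar$year[i],
             instance = ifelse(is.na(i), NA,
                               paste(calendar$label[i], calendar$year[i],
                                     sep = "-")),
             stringsAsFactors = FALSE)
}

#' Stratification onset and breakdown dates
#'
#' Onset is the first date beginning a run of at least `k` consecutive days
#' with surface minus experienced temperature greater than `delta`; breakdown
#' is the first later date beginning a `k`-day run with the difference back
#' at or below `delta`.
#'
#' @param surface,experienced daily series (`date`, `temperature`) covering
#'   the same dates.
#' @param delta separation threshold (degC, default 1).
#' @param k run length in days (default 5).
#' @return list `onset`, `breakdown` (Dates; `NA` with a warning if the lake
#'   never stratifies under these settings).
#' @export
stratification_breakpoints <- function(surface, experienced, delta = 1, k = 5) {
  m <- merge(surface, experienced, by = "date",
             suffixes = c("_surface", "_experienced"))
  m <- m[order(m$date), ]
  diffv <- m$temperature_surface - m$temperature_experienced
  onset <- run_start(diffv > delta, k)
  if (is.na(onset)) {
    warning("no stratification period found (delta = ", delta, ")")
    return(list(onset = as.Date(NA), breakdown = as.Date(NA)))
  }
  after <- seq_along(diffv) > onset
  breakdown <- run_start(diffv <= delta & after, k)
  list(onset = m$date[onset],
       breakdown = if (is.na(breakdown)) as.Date(NA) else m$date[breakdown])
}

# index of first element starting >= k consecutive TRUEs, or NA
run_start <- function(flag, k) {
  r <- rle(flag)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  sum(r$lengths[seq_len(hit[1] - 1L)]) + 1L
}

#' Write / read a season calendar as CSV
#'
#' Columns `start,end,label` with ISO dates; `end` is exclusive.
#' @param calendar a `season_calendar`.
#' @param path file path.
#' @return `path` invisibly / the calendar.
#' @export
write_calendar <- function(calendar, path) {
  write.csv(calendar[, c("start", "end", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calendar
#' @export
read_calendar <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  cal <- data.frame(start = as.Date(d$start), end = as.Date(d$end),
                    label = d$label,
                    year = as.integer(format(as.Date(d$start), "%Y")),
                    stringsAsFactors = FALSE)
  class(cal) <- c("season_calendar", "data.frame")
  cal
}
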