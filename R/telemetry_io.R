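# Detection/fish/receiver table I/O and the five-step cleaning cascade:
# spurious singles -> dead fish -> release-season / study-window clips ->
# full-season coverage. Filters never reorder surviving rows and never alter
# field values, so the cascade is idempotent.

DET_COLS <- c("tag", "receiver", "timestamp")

# lenient per-element ISO-8601 parser: NA for malformed rows instead of the
# all-or-nothing error base as.POSIXct gives
parse_timestamps <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read a detection table
#'
#' CSV dialect: columns `tag`, `receiver`, `timestamp` (ISO-8601 UTC) and
#' optional `depth`, `temperature`. Malformed timestamps are counted, logged
#' via `message()`, and skipped. Rows come back sorted by (tag, timestamp).
#'
#' @param path CSV file path.
#' @return data.frame of detections with attribute `skipped` (rows dropped).
#' @export
read_detections <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DET_COLS, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ts <- parse_timestamps(d$timestamp)
  bad <- is.na(ts)
  if (any(bad))
    message(sum(bad), " row(s) with unparseable timestamps skipped")
  d <- d[!bad, , drop = FALSE]
  d$timestamp <- ts[!bad]
  if (is.null(d$depth)) d$depth <- NA_real_
  if (is.null(d$temperature)) d$temperature <- NA_real_
  d <- d[order(d$tag, d$timestamp), ]
  rownames(d) <- NULL
  attr(d, "skipped") <- sum(bad)
  d
}

#' @rdname read_detections
#' @param detections detection data.frame to write.
#' @export
write_detections <- function(detections, path) {
  out <- detections
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read fish and receiver metadata tables
#'
#' Fish CSV: `fish`, `tag`, `origin` (stocked|wild), `transmitter`
#' (sensor|plain), `capture_date`, `capture_length`, `capture_method`,
#' `capture_region`. Receiver CSV: `receiver`, `station`, `x`, `y`,
#' `station_depth`, `deploy_start`, `deploy_end`, `region`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_fish <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish", "tag", "origin", "transmitter", "capture_date",
            "capture_length")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(all(d$origin %in% c("stocked", "wild")),
            all(d$transmitter %in% c("sensor", "plain")),
            all(d$capture_length > 0))
  d$capture_date <- as.Date(d$capture_date)
  d
}

#' @rdname read_fish
#' @export
read_receivers <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$deploy_start <- as.POSIXct(d$deploy_start, tz = "UTC")
  d$deploy_end <- as.POSIXct(d$deploy_end, tz = "UTC")
  d
}

new_filter_report <- function(rule, removed_rows, input_rows, output_rows,
                              flagged_fish = character(),
                              dropped_fish = character()) {
  structure(list(rule = rule, removed = removed_rows, input = input_rows,
                 output = output_rows,
                 fraction_removed = if (input_rows > 0)
                   removed_rows / input_rows else 0,
                 flagged_fish = flagged_fish, dropped_fish = dropped_fish),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: removed %d of %d rows (%.2f%%)\n",
              x$rule, x$removed, x$input, 100 * x$fraction_removed))
  if (length(x$flagged_fish))
    cat("  flagged fish:", paste(x$flagged_fish, collapse = ", "), "\n")
  if (length(x$dropped_fish))
    cat("  dropped fish:", paste(x$dropped_fish, collapse = ", "), "\n")
  invisible(x)
}

#' Remove spurious single detections
#'
#' A detection is spurious when no other detection of the same tag at the
#' same receiver falls within one hour of it on either side (a lone ping over
#' a period longer than 1 h). Ties at exactly 1 h count as neighbours.
#'
#' @param detections detection data.frame sorted by (tag, timestamp).
#' @return list `detections` (survivors, order preserved), `report`
#'   (a `filter_report`).
#' @export
filter_spurious <- function(detections) {
  n <- nrow(detections)
  if (n == 0L)
    return(list(detections = detections,
                report = new_filter_report("spurious", 0L, 0L, 0L)))
  key <- paste(detections$tag, detections$receiver, sep = "\r")
  keep <- logical(n)
  for (ix in split(seq_len(n), key)) {
    tt <- sort(as.numeric(detections$timestamp[ix]))
    o <- order(as.numeric(detections$timestamp[ix]))
    gap_prev <- c(Inf, diff(tt))
    gap_next <- c(diff(tt), Inf)
    ok <- (gap_prev <= 3600) | (gap_next <= 3600)
    keep[ix[o]] <- ok
  }
  out <- detections[keep, , drop = FALSE]
  list(detections = out,
       report = new_filter_report("spurious", n - nrow(out), n, nrow(out)))
}

#' Flag dead fish
#'
#' A fish is flagged dead when (a) it carries a sensor tag and the standard
#' deviation of all its depth records is below `depth_sd_m` (no vertical
#' activity), or (b) its final run of detections sits at a single station
#' continuously for at least `terminal_days` days up to the end of its
#' record. Receiver-to-station mapping comes from `receivers` when given;
#' otherwise each receiver is its own station.
#'
#' @param detections cleaned detection data.frame.
#' @param fish fish metadata (needs `fish`, `tag`, `transmitter`).
#' @param receivers optional receiver table for station mapping.
#' @param terminal_days rule (b) duration D (days, default 30); unstated in
#'   the field protocol, hence configurable.
#' @param depth_sd_m rule (a) threshold (default 1 m).
#' @return list `fish` (with logical `dead` and `dead_rule` columns),
#'   `detections` (flagged fish's rows removed), `report`.
#' @export
flag_dead <- function(detections, fish, receivers = NULL,
                      terminal_days = 30, depth_sd_m = 1) {
  station <- if (!is.null(receivers))
    receivers$station[match(detections$receiver, receivers$receiver)]
  else detections$receiver
  fish$dead <- FALSE
  fish$dead_rule <- NA_character_
  for (i in seq_len(nrow(fish))) {
    ix <- which(detections$tag == fish$tag[i])
    if (!length(ix)) next
    o <- ix[order(detections$timestamp[ix])]
    if (fish$transmitter[i] == "sensor") {
      dep <- detections$depth[o]
      dep <- dep[!is.na(dep)]
      if (length(dep) >= 2 && sd(dep) < depth_sd_m) {
        fish$dead[i] <- TRUE; fish$dead_rule[i] <- "no_vertical_activity"
        next
      }
    }
    st <- station[o]
    last_change <- max(c(0L, which(st[-1L] != st[-length(st)])))
    run_start_t <- detections$timestamp[o][last_change + 1L]
    run_end_t <- detections$timestamp[o][length(o)]
    span_days <- as.numeric(difftime(run_end_t, run_start_t, units = "days"))
    if (span_days >= terminal_days) {
      fish$dead[i] <- TRUE; fish$dead_rule[i] <- "terminal_residency"
    }
  }
  dead_tags <- fish$tag[fish$dead]
  keep <- !(detections$tag %in% dead_tags)
  out <- detections[keep, , drop = FALSE]
  list(fish = fish, detections = out,
       report = new_filter_report("dead_fish", nrow(detections) - nrow(out),
                                  nrow(detections), nrow(out),
                                  flagged_fish = fish$fish[fish$dead]))
}

#' Apply cohort filters
#'
#' Three rules, in order: (1) drop each fish's detections during its release
#' season (the calendar interval containing its capture date); (2) clip all
#' detections to the half-open study window `[start, end)`; (3) drop fish
#' whose remaining detection record does not span at least one complete
#' season (first detection at or before a season start and last detection at
#' or after its end).
#'
#' @param detections cleaned detection data.frame.
#' @param fish fish metadata with `capture_date`.
#' @param calendar a `season_calendar` covering capture dates and the window.
#' @param window length-2 POSIXct (or Date) study window.
#' @return list `detections`, `fish` (with `insufficient_coverage` flag),
#'   `reports` (one `filter_report` per rule).
#' @export
apply_cohort_filters <- function(detections, fish, calendar, window) {
  window <- as.POSIXct(window, tz = "UTC")
  n0 <- nrow(detections)

  rel <- season_at(calendar, fish$capture_date)
  if (anyNA(rel$label))
    stop("fish capture date outside calendar: ",
         paste(fish$fish[is.na(rel$label)], collapse = ", "), call. = FALSE)
  det_season <- season_at(calendar, detections$timestamp)
  rel_inst <- rel$instance[match(detections$tag, fish$tag)]
  keep1 <- is.na(det_season$instance) | det_season$instance != rel_inst
  keep1[is.na(keep1)] <- TRUE
  d1 <- detections[keep1, , drop = FALSE]
  r1 <- new_filter_report("release_season", n0 - nrow(d1), n0, nrow(d1))

  keep2 <- d1$timestamp >= window[1] & d1$timestamp < window[2]
  d2 <- d1[keep2, , drop = FALSE]
  r2 <- new_filter_report("study_window", nrow(d1) - nrow(d2), nrow(d1),
                          nrow(d2))

  # full-season coverage: detection record must bracket a whole season
  cal_s <- as.POSIXct(paste(calendar$start, "00:00:00"), tz = "UTC")
  cal_e <- as.POSIXct(paste(calendar$end, "00:00:00"), tz = "UTC")
  span <- vapply(split(as.numeric(d2$timestamp), d2$tag),
                 function(v) c(min(v), max(v)), numeric(2))
  covered <- function(tag) {
    if (!tag %in% colnames(span)) return(FALSE)
    lo <- span[1, tag]; hi <- span[2, tag]
    any(as.numeric(cal_s) >= lo & as.numeric(cal_e) <= hi)
  }
  fish$insufficient_coverage <- !vapply(fish$tag, covered, logical(1))
  dropped <- fish$tag[fish$insufficient_coverage]
  keep3 <- !(d2$tag %in% dropped)
  d3 <- d2[keep3, , drop = FALSE]
  r3 <- new_filter_report("full_season", nrow(d2) - nrow(d3), nrow(d2),
                          nrow(d3),
                          dropped_fish = fish$fish[fish$insufficient_coverage])
  list(detections = d3, fish = fish, reports = list(r1, r2, r3))
}

#' Run the full cleaning cascade
#'
#' spurious -> dead -> cohort filters, in the fixed field order (the dead
#' rule sees spurious-cleaned data; the full-season check runs last).
#'
#' @inheritParams apply_cohort_filters
#' @inheritParams flag_dead
#' @return list `detections`, `fish`, `reports` (named list of
#'   `filter_report`s).
#' @export
filter_cascade <- function(detections, fish, calendar, window,
                           receivers = NULL, terminal_days = 30,
                           depth_sd_m = 1) {
  s1 <- filter_spurious(detections)
  s2 <- flag_dead(s1$detections, fish, receivers, terminal_days, depth_sd_m)
  s3 <- apply_cohort_filters(s2$detections, s2$fish, calendar, window)
  list(detections = s3$detections, fish = s3$fish,
       reports = c(list(spurious = s1$report, dead = s2$report),
                   setNames(s3$reports,
                            c("release_season", "study_window",
                              "full_season"))))
}

#' Join receiver metadata onto detections
#'
#' Adds `station`, `x`, `y`, `station_depth` and `region` columns.
#'
#' @param detections detection data.frame.
#' @param receivers receiver table.
#' @return detections with receiver columns joined; unknown receivers raise
#'   an error.
#' @export
join_receivers <- function(detections, receivers) {
  i <- match(detections$receiver, receivers$receiver)
  if (anyNA(i))
    stop("detections at unknown receiver(s): ",
         paste(unique(detections$receiver[is.na(i)]), collapse = ", "),
         call. = FALSE)
  detections$station <- receivers$station[i]
  detections$x <- receivers$x[i]
  detections$y <- receivers$y[i]
  detections$station_depth <- receivers$station_depth[i]
  detections$region <- receivers$region[i]
  detections
}
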