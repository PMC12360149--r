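# Synthetic-lake dataset generator: fish tracks, temperature series and
# detection tables with the statistical structure the downstream analysis
# assumes. Everything is driven by one SimConfig and a single global seed;
# per-fish sub-streams keep tracks reproducible under reordering.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-lake generator. Defaults state the
#' conditions the analysis assumes: tags transmit with a uniform random delay
#' of 80-160 s; detection efficiency is ~70% at 250 m and ~30% at 500 m,
#' joined by a two-parameter logistic; fish walk at season- and
#' origin-specific speeds with seasonal depth preferences.
#'
#' @param seed integer master seed; all sub-streams derive from it.
#' @param n_fish named integer vector, fish per origin
#'   (default `c(stocked = 10, wild = 10)`).
#' @param speed_km_day named list `origin -> named numeric by season label`
#'   (km/day); a plain numeric is recycled to all origins/seasons.
#' @param depth_mean,depth_sd seasonal depth preference (m), same recycling
#'   rules as `speed_km_day`.
#' @param delay_s length-2 numeric, uniform transmission-delay bounds in
#'   seconds (default `c(80, 160)`).
#' @param de_calibration two-column matrix/data.frame of (range m,
#'   detection probability) calibration points, strictly decreasing in range;
#'   default `rbind(c(250, 0.70), c(500, 0.30))`.
#' @param step_minutes internal walk step (default 10 min).
#' @param turn_sd sd of the per-step heading change in radians (0 gives
#'   straight-line swimmers; default 0.6).
#' @param occupancy_target optional named numeric of region weights; each
#'   fish draws a target region per residency bout from these weights and
#'   biases its walk toward it, producing known long-run regional occupancy.
#' @param target_block_days length of a residency bout in days (default 3):
#'   lake fish hold multi-day site fidelity, and longer bouts keep transit
#'   time a small fraction of the schedule.
#' @param depth_jitter_sd within-day depth wobble (m, default 2) around the
#'   fish's daily depth; gives live sensor fish vertical activity.
#' @param window length-2 POSIXct/Date study window `[start, end)`.
#' @param de_mode `"logistic"` (default): each in-range active receiver
#'   detects independently with the calibrated probability; `"nearest"`:
#'   noise-free validation mode where each transmission is logged by exactly
#'   the nearest active receiver within the 50% detection range (no
#'   multi-receiver jitter, so centre-of-activity estimates are bounded by
#'   the true track).
#' @param dead_fish optional planted dead fish: a character vector of fish
#'   ids (death at one third of the track) or a named numeric vector mapping
#'   fish id to the track fraction at which death occurs (0 = dead on
#'   release, giving zero vertical activity for sensor tags). From death the
#'   fish stops moving and reports a constant depth.
#' @param sensor_fraction fraction of fish per origin carrying
#'   depth/temperature sensor tags (default 0.5).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_fish = c(stocked = 10L, wild = 10L),
                       speed_km_day = 3,
                       depth_mean = 25, depth_sd = 8,
                       delay_s = c(80, 160),
                       de_calibration = rbind(c(250, 0.70), c(500, 0.30)),
                       step_minutes = 10,
                       turn_sd = 0.6,
                       occupancy_target = NULL,
                       target_block_days = 3,
                       depth_jitter_sd = 2,
                       de_mode = c("logistic", "nearest"),
                       window = as.POSIXct(c("2021-01-01", "2022-01-01"),
                                           tz = "UTC"),
                       dead_fish = character(),
                       sensor_fraction = 0.5) {
  stopifnot(delay_s[1] > 0, delay_s[1] < delay_s[2],
            all(de_calibration[, 2] > 0), all(de_calibration[, 2] < 1))
  de_calibration <- as.matrix(de_calibration)
  if (is.unsorted(de_calibration[, 1]) ||
      any(diff(de_calibration[, 2]) >= 0))
    stop("detection calibration must be strictly decreasing in range",
         call. = FALSE)
  de_mode <- match.arg(de_mode)
  structure(list(seed = as.integer(seed), n_fish = n_fish,
                 speed_km_day = speed_km_day,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 delay_s = delay_s, de_calibration = de_calibration,
                 step_minutes = step_minutes, turn_sd = turn_sd,
                 occupancy_target = occupancy_target,
                 target_block_days = target_block_days,
                 depth_jitter_sd = depth_jitter_sd,
                 de_mode = de_mode,
                 window = as.POSIXct(window, tz = "UTC"),
                 dead_fish = dead_fish,
                 sensor_fraction = sensor_fraction),
            class = "sim_config")
}

# Derived 32-bit sub-seed; i indexes the sub-stream.
sub_seed <- function(seed, i) as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)

#' Two-parameter logistic detection-efficiency curve
#'
#' Fits `p(r) = 1 / (1 + exp((r - r50) / s))` exactly through two calibration
#' points; with the defaults (250 m, 0.70) and (500 m, 0.30) this gives
#' r50 = 375 m. The curve is monotone non-increasing in range for any valid
#' calibration.
#'
#' @param calibration two-row matrix of (range m, probability).
#' @return list with `r50`, `s` and function `p(range_m)`.
#' @export
de_logistic <- function(calibration) {
  calibration <- as.matrix(calibration)
  stopifnot(nrow(calibration) == 2L)
  r <- calibration[, 1]; l <- qlogis(calibration[, 2])
  # logit p = -(r - r50)/s  => slope -1/s, intercept r50/s
  s <- (r[2] - r[1]) / (l[1] - l[2])
  r50 <- r[1] + s * l[1]
  list(r50 = r50, s = s,
       p = function(range_m) plogis(-(range_m - r50) / s))
}

season_param <- function(par, origin, label) {
  if (is.list(par)) par <- par[[origin]]
  if (length(names(par)) && label %in% names(par)) return(unname(par[[label]]))
  unname(par[[1]])
}

#' Simulate fish tracks
#'
#' Biased correlated random walk at `step_minutes` resolution, constrained to
#' water by rejection sampling of headings (bounded retries, then the fish
#' holds position for that step). Step length is fixed at
#' `speed * step / day`, so realized track length matches the configured
#' seasonal speed. Daily depth is drawn from the seasonal normal preference
#' truncated to `[0, bottom depth]`; within-day values wobble by
#' `depth_jitter_sd`. When `occupancy_target` is set, each fish redraws a
#' target region daily and steers toward its centroid while outside it.
#' Fish listed in `dead_fish` freeze mid-window (position and depth constant).
#'
#' @param lake a `lake_geometry`.
#' @param calendar a `season_calendar` covering the study window (see
#'   [classify_seasons()]).
#' @param config a [sim_config()].
#' @return object of class `true_tracks`: list of per-fish tracks, each with
#'   `fish`, `origin`, `sensor`, `path` (data.frame `time`, `x`, `y`,
#'   `depth`, `region`, `season`, `year`) and `truth` (per season-instance
#'   distance km, occupancy proportions, mean depth).
#' @export
simulate_fish <- function(lake, calendar, config) {
  stopifnot(inherits(lake, "lake_geometry"), inherits(config, "sim_config"))
  win <- config$window
  step_s <- config$step_minutes * 60
  times <- seq(win[1], win[2], by = step_s)
  if (length(times) < 2L) stop("study window shorter than one step")
  dates <- as.Date(times, tz = "UTC")
  sl <- season_at(calendar, dates)

  origins <- rep(names(config$n_fish), config$n_fish)
  ids <- sprintf("F%03d", seq_along(origins))
  sensors <- unlist(lapply(config$n_fish, function(n) {
    k <- round(n * config$sensor_fraction)
    c(rep(TRUE, k), rep(FALSE, n - k))
  }), use.names = FALSE)

  region_ctr <- t(vapply(lake$regions, colMeans, numeric(2)))
  tracks <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(sub_seed(config$seed, i))
    df <- config$dead_fish
    dead_frac <- if (is.numeric(df) && ids[i] %in% names(df))
      unname(df[ids[i]])
    else if (is.character(df) && ids[i] %in% df) 1 / 3
    else NA_real_
    tracks[[i]] <- simulate_one_track(
      lake, config, ids[i], origins[i], sensors[i],
      times, dates, sl, region_ctr, dead_frac = dead_frac)
  }
  structure(tracks, class = "true_tracks", names = ids)
}

simulate_one_track <- function(lake, config, id, origin, sensor,
                               times, dates, sl, region_ctr, dead_frac) {
  dead <- !is.na(dead_frac)
  n <- length(times)
  dt_day <- config$step_minutes / 1440
  x <- numeric(n); y <- numeric(n)
  # random start in water
  repeat {
    p0 <- c(runif(1, lake$bbox["xmin"], lake$bbox["xmax"]),
            runif(1, lake$bbox["ymin"], lake$bbox["ymax"]))
    if (is_water(lake, matrix(p0, ncol = 2))) break
  }
  x[1] <- p0[1]; y[1] <- p0[2]
  heading <- runif(1, 0, 2 * pi)

  # daily schedule: target region and preferred depth
  udates <- unique(dates)
  day_idx <- match(dates, udates)
  tgt <- NULL
  if (!is.null(config$occupancy_target)) {
    w <- config$occupancy_target
    blocks <- ceiling(seq_along(udates) / config$target_block_days)
    per_block <- sample(names(w), max(blocks), replace = TRUE, prob = w)
    tgt <- per_block[blocks]
  }
  death_at <- if (dead) max(1L, floor(n * dead_frac)) else n + 1L

  speeds <- vapply(sl$label, function(lb)
    season_param(config$speed_km_day, origin, lb), numeric(1))
  step_len <- speeds * 1000 * dt_day

  cur_reg <- point_region(lake, matrix(c(x[1], y[1]), ncol = 2))
  for (t in 2:n) {
    if (t > death_at) { x[t] <- x[t - 1]; y[t] <- y[t - 1]; next }
    L <- step_len[t]
    if (L <= 0) { x[t] <- x[t - 1]; y[t] <- y[t - 1]; next }
    if (!is.null(tgt) && !is.na(cur_reg) && tgt[day_idx[t]] != cur_reg) {
      ctr <- region_ctr[tgt[day_idx[t]], ]
      heading <- atan2(ctr[2] - y[t - 1], ctr[1] - x[t - 1]) + rnorm(1, 0, 0.3)
    } else {
      heading <- heading + rnorm(1, 0, config$turn_sd)
    }
    placed <- FALSE
    h <- heading
    for (try in 1:24) {
      nx <- x[t - 1] + L * cos(h); ny <- y[t - 1] + L * sin(h)
      if (is_water(lake, matrix(c(nx, ny), ncol = 2))) {
        x[t] <- nx; y[t] <- ny; heading <- h; placed <- TRUE; break
      }
      h <- runif(1, 0, 2 * pi)
    }
    if (!placed) { x[t] <- x[t - 1]; y[t] <- y[t - 1] }
    else cur_reg <- point_region(lake, matrix(c(x[t], y[t]), ncol = 2))
  }

  region <- point_region(lake, cbind(x, y))
  bottom <- lake_depth_at(lake, cbind(x, y))
  bottom[is.na(bottom)] <- max(lake$region_depth)

  # daily preferred depth, truncated to local bottom
  dmean <- vapply(sl$label, function(lb)
    season_param(config$depth_mean, origin, lb), numeric(1))
  dsd <- vapply(sl$label, function(lb)
    season_param(config$depth_sd, origin, lb), numeric(1))
  first_of_day <- !duplicated(day_idx)
  day_depth_draw <- rnorm(length(udates))
  day_depth <- (dmean[first_of_day] + day_depth_draw * dsd[first_of_day])[day_idx]
  depth <- day_depth + rnorm(n, 0, config$depth_jitter_sd)
  depth <- pmin(pmax(depth, 0), bottom)
  if (dead) {
    frozen <- min(death_at, n)
    depth[seq(frozen, n)] <- depth[frozen]
  }

  path <- data.frame(time = times, x = x, y = y, depth = depth,
                     region = region, season = sl$label, year = sl$year,
                     stringsAsFactors = FALSE)
  truth <- track_truth(path)
  list(fish = id, origin = origin, sensor = sensor, path = path,
       truth = truth)
}

# Per season-instance ground truth: distance, occupancy, mean depth.
track_truth <- function(path) {
  n <- nrow(path)
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2) / 1000
  inst <- paste(path$season, path$year, sep = "-")
  out <- lapply(split(seq_len(n), inst), function(ix) {
    pair <- ix[-length(ix)]
    pair <- pair[ix[-1L] == pair + 1L]
    occ <- table(factor(path$region[ix]))
    occ <- occ / sum(occ)
    data.frame(season = path$season[ix[1]], year = path$year[ix[1]],
               distance_km = sum(seg[pair]),
               max_occupancy = if (length(occ)) max(occ) else NA_real_,
               top_region = if (length(occ)) names(occ)[which.max(occ)] else NA,
               mean_depth = mean(path$depth[ix]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate detection records
#'
#' Transmission times per fish are cumulative sums of independent
#' uniform(80 s, 160 s) delays from the track start. Each transmission is
#' detected independently by every active in-range receiver with probability
#' from the logistic calibration curve. Sensor tags carry the track's depth
#' and, when a temperature series is supplied, the experienced temperature of
#' the day (small sensor noise added).
#'
#' @param tracks a `true_tracks` object from [simulate_fish()].
#' @param receivers data.frame with columns `receiver`, `station`, `x`, `y`,
#'   `station_depth`, `deploy_start`, `deploy_end`, `region`.
#' @param config a [sim_config()].
#' @param temperature optional data.frame `date`, `temperature` (experienced
#'   series) feeding sensor-tag temperature values.
#' @param temp_noise_sd sensor temperature noise sd (default 0.1 degC).
#' @return data.frame of detections (`tag`, `receiver`, `timestamp`, `depth`,
#'   `temperature`) sorted by timestamp. Empty with a warning if no receiver
#'   is active in the window.
#' @export
simulate_detections <- function(tracks, receivers, config,
                                temperature = NULL, temp_noise_sd = 0.1) {
  stopifnot(inherits(tracks, "true_tracks"), nrow(receivers) > 0)
  de <- de_logistic(config$de_calibration)
  max_range <- de$r50 + de$s * log(1 / 1e-4 - 1)  # p < 1e-4 beyond this
  rs <- as.POSIXct(receivers$deploy_start, tz = "UTC")
  re <- as.POSIXct(receivers$deploy_end, tz = "UTC")

  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    set.seed(sub_seed(config$seed, 500000L + i))
    t0 <- as.numeric(tr$path$time[1])
    t1 <- as.numeric(tr$path$time[nrow(tr$path)])
    ndel <- ceiling((t1 - t0) / config$delay_s[1]) + 1L
    tx <- t0 + cumsum(runif(ndel, config$delay_s[1], config$delay_s[2]))
    tx <- tx[tx <= t1]
    if (!length(tx)) next
    px <- approx(as.numeric(tr$path$time), tr$path$x, tx)$y
    py <- approx(as.numeric(tr$path$time), tr$path$y, tx)$y
    pd <- approx(as.numeric(tr$path$time), tr$path$depth, tx)$y
    if (config$de_mode == "nearest") {
      bestd <- rep(Inf, length(tx)); bestj <- rep(NA_integer_, length(tx))
      for (j in seq_len(nrow(receivers))) {
        act <- tx >= as.numeric(rs[j]) & tx < as.numeric(re[j])
        if (!any(act)) next
        d <- sqrt((px - receivers$x[j])^2 + (py - receivers$y[j])^2)
        upd <- act & d < bestd
        bestd[upd] <- d[upd]; bestj[upd] <- j
      }
      det_ix <- which(bestd <= de$r50)
      out[[i]] <- if (length(det_ix))
        data.frame(tag = tr$fish,
                   receiver = receivers$receiver[bestj[det_ix]],
                   timestamp = tx[det_ix],
                   depth = if (tr$sensor) pd[det_ix] else NA_real_,
                   stringsAsFactors = FALSE)
    } else {
      hits <- vector("list", nrow(receivers))
      for (j in seq_len(nrow(receivers))) {
        act <- tx >= as.numeric(rs[j]) & tx < as.numeric(re[j])
        if (!any(act)) next
        d <- sqrt((px - receivers$x[j])^2 + (py - receivers$y[j])^2)
        cand <- which(act & d <= max_range)
        if (!length(cand)) next
        det <- cand[runif(length(cand)) < de$p(d[cand])]
        if (!length(det)) next
        hits[[j]] <- data.frame(tag = tr$fish,
                                receiver = receivers$receiver[j],
                                timestamp = tx[det],
                                depth = if (tr$sensor) pd[det] else NA_real_,
                                stringsAsFactors = FALSE)
      }
      out[[i]] <- do.call(rbind, hits)
    }
  }
  det <- do.call(rbind, out)
  if (is.null(det) || nrow(det) == 0L) {
    warning("no detections simulated (no receiver active in window?)")
    det <- data.frame(tag = character(), receiver = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      depth = numeric(), temperature = numeric())
    return(det)
  }
  det$timestamp <- as.POSIXct(det$timestamp, origin = "1970-01-01", tz = "UTC")
  det$temperature <- NA_real_
  if (!is.null(temperature)) {
    sensor <- !is.na(det$depth)
    dte <- as.Date(det$timestamp[sensor], tz = "UTC")
    tv <- temperature$temperature[match(dte, as.Date(temperature$date))]
    set.seed(sub_seed(config$seed, 999999L))
    det$temperature[sensor] <- tv + rnorm(sum(sensor), 0, temp_noise_sd)
  }
  det <- det[order(det$timestamp, det$tag, det$receiver), ]
  rownames(det) <- NULL
  det
}

#' Simulate daily surface and experienced temperature series
#'
#' Surface temperature follows a smooth annual sinusoid between `tmin` and
#' `tmax` (coldest at `phase_min` day-of-year). The experienced series equals
#' the surface series while the surface is at or below the stratification
#' threshold; above it the experienced temperature rises with reduced slope
#' (`strat_slope`) and is capped at the hypolimnion temperature — so the two
#' series deviate from the first day the surface exceeds the threshold, and
#' the separation is largest in mid-summer.
#'
#' @param dates Date vector (daily).
#' @param tmin,tmax annual surface extremes (degC, defaults 2 and 24).
#' @param phase_min day-of-year of the surface minimum (default 35).
#' @param strat_threshold surface temperature at which stratification begins
#'   (degC, default 8).
#' @param hypolimnion_cap experienced-temperature ceiling under
#'   stratification (degC, default 9).
#' @param strat_slope d(experienced)/d(surface) just above the threshold
#'   (default 0.25).
#' @return list of two data.frames `surface` and `experienced`, each
#'   `date`, `temperature`, with a `role` attribute.
#' @export
simulate_temperature <- function(dates,
                                 tmin = 2, tmax = 24, phase_min = 35,
                                 strat_threshold = 8, hypolimnion_cap = 9,
                                 strat_slope = 0.25) {
  doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
  mid <- (tmin + tmax) / 2; amp <- (tmax - tmin) / 2
  surf <- mid - amp * cos(2 * pi * (doy - phase_min) / 365.25)
  expd <- ifelse(surf <= strat_threshold, surf,
                 pmin(hypolimnion_cap,
                      strat_threshold + strat_slope * (surf - strat_threshold)))
  s <- data.frame(date = dates, temperature = surf)
  e <- data.frame(date = dates, temperature = expd)
  attr(s, "role") <- "surface"; attr(e, "role") <- "experienced"
  list(surface = s, experienced = e)
}

#' Build a fish metadata table for simulated tracks
#'
#' @param tracks a `true_tracks` object.
#' @param capture_date Date of capture/release (default the window start).
#' @param capture_length_mm named numeric of mean capture length per origin
#'   (default `c(stocked = 450, wild = 450)`); individual lengths jitter by
#'   `length_sd`.
#' @param length_sd sd of capture length (default 60 mm).
#' @param seed integer seed for the length draw.
#' @return data.frame matching the FishRecord contract: `fish`, `tag`,
#'   `origin`, `transmitter` ("sensor"/"plain"), `capture_date`,
#'   `capture_length`, `capture_method`, `capture_region`.
#' @export
make_fish_table <- function(tracks, capture_date = NULL,
                            capture_length_mm = c(stocked = 450, wild = 450),
                            length_sd = 60, seed = 1L) {
  stopifnot(inherits(tracks, "true_tracks"))
  set.seed(sub_seed(seed, 424243L))
  if (is.null(capture_date))
    capture_date <- as.Date(tracks[[1]]$path$time[1], tz = "UTC")
  data.frame(
    fish = vapply(tracks, `[[`, "", "fish"),
    tag = vapply(tracks, `[[`, "", "fish"),
    origin = vapply(tracks, `[[`, "", "origin"),
    transmitter = ifelse(vapply(tracks, `[[`, NA, "sensor"),
                         "sensor", "plain"),
    capture_date = capture_date,
    capture_length = round(capture_length_mm[
      vapply(tracks, `[[`, "", "origin")] +
      rnorm(length(tracks), 0, length_sd)),
    capture_method = "angling",
    capture_region = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Lay out a regular receiver array over the water
#'
#' Receivers on a square grid clipped to water; a convenience for building
#' dense or sparse synthetic arrays.
#'
#' @param lake a `lake_geometry`.
#' @param spacing grid spacing (m).
#' @param window length-2 POSIXct deployment interval for every receiver.
#' @param station_depth receiver station depth (m), recycled.
#' @return receiver data.frame (see [simulate_detections()]).
#' @export
make_receiver_grid <- function(lake, spacing, window, station_depth = 50) {
  xs <- seq(lake$bbox["xmin"] + spacing / 2, lake$bbox["xmax"], by = spacing)
  ys <- seq(lake$bbox["ymin"] + spacing / 2, lake$bbox["ymax"], by = spacing)
  g <- expand.grid(x = xs, y = ys)
  reg <- point_region(lake, as.matrix(g))
  g <- g[!is.na(reg), , drop = FALSE]
  reg <- reg[!is.na(reg)]
  data.frame(receiver = sprintf("R%04d", seq_len(nrow(g))),
             station = sprintf("S%04d", seq_len(nrow(g))),
             x = g$x, y = g$y,
             station_depth = rep_len(station_depth, nrow(g)),
             deploy_start = as.POSIXct(window[1], tz = "UTC"),
             deploy_end = as.POSIXct(window[2], tz = "UTC"),
             region = reg, stringsAsFactors = FALSE, row.names = NULL)
}
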