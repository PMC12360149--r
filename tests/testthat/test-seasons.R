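test_that("daily experienced temperature: per-fish minima then cross-fish mean", {
  d <- make_dets(
    det_row("A", "R1", "2021-06-01 01:00:00", temperature = 10),
    det_row("A", "R1", "2021-06-01 05:00:00", temperature = 8),
    det_row("A", "R1", "2021-06-01 09:00:00", temperature = 12))
  expect_equal(daily_experienced(d)$temperature, 8)
  d2 <- rbind(d, make_dets(
    det_row("B", "R2", "2021-06-01 02:00:00", temperature = 10),
    det_row("B", "R2", "2021-06-01 03:00:00", temperature = 6)))
  expect_equal(daily_experienced(d2)$temperature, (8 + 6) / 2)
  expect_error(daily_experienced(det_row("A", "R1", "2021-06-01 01:00:00")),
               "sensor")
})

test_that("experienced-series recovery: stratified summer sits at the cap", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  tmp <- simulate_temperature(dates)
  cal <- classify_seasons(smooth_series(tmp$surface))
  summer <- cal[cal$label == "summer", ][1, ]
  # mid-summer block, away from edges
  mid <- tmp$experienced$date >= summer$start + 20 &
    tmp$experienced$date < summer$end - 20
  expect_true(all(abs(tmp$experienced$temperature[mid] - 9) < 1e-9))
})

test_that("rolling mean: constant series, step mean, identity window", {
  s <- data.frame(date = as.Date("2021-01-01") + 0:9, temperature = 5)
  expect_equal(smooth_series(s, 7)$temperature, rep(5, 10))
  step <- data.frame(date = as.Date("2021-01-01") + 0:13,
                     temperature = rep(c(0, 14), each = 7))
  sm <- smooth_series(step, 7)
  # centred window at the day of the step: 3 zeros + 4 fourteens
  expect_equal(sm$temperature[8], mean(c(0, 0, 0, 14, 14, 14, 14)))
  expect_equal(smooth_series(step, 1)$temperature, step$temperature)
  expect_error(smooth_series(step, 4), "window")
})

test_that("season state machine matches a day-by-day oracle on known crossings", {
  # piecewise series with crossings planted at exact days
  n <- 365
  tv <- numeric(n)
  tv[1:109] <- 4                     # winter
  tv[110:149] <- 10                  # >= 8 on day 110 -> spring
  tv[150:269] <- 20                  # > 17 on day 150 -> summer
  tv[270:309] <- 12                  # < 15 on day 270 -> fall
  tv[310:365] <- 4                   # < 8 on day 310 -> winter
  d0 <- as.Date("2021-01-01")
  series <- data.frame(date = d0 + 0:(n - 1), temperature = tv)
  cal <- classify_seasons(series)      # unsmoothed: crossings are planted
  expect_equal(cal$label, c("winter", "spring", "summer", "fall", "winter"))
  expect_equal(cal$start, d0 + c(0, 109, 149, 269, 309))
  expect_equal(cal$end, d0 + c(109, 149, 269, 309, 365))
  # intervals partition the range
  expect_equal(sum(as.numeric(cal$end - cal$start)), n)
  expect_true(all(cal$end[-nrow(cal)] == cal$start[-1]))
})

test_that("all-cold series yields a single winter; warm-less year warns", {
  d0 <- as.Date("2021-01-01")
  cold <- data.frame(date = d0 + 0:99, temperature = 4)
  cal <- classify_seasons(cold)
  expect_equal(nrow(cal), 1L)
  expect_equal(cal$label, "winter")
  # spring that never reaches 17 closes directly as winter, with a warning
  tv <- c(rep(4, 50), rep(10, 60), rep(4, 50))
  lukewarm <- data.frame(date = d0 + seq_along(tv) - 1, temperature = tv)
  expect_warning(cal2 <- classify_seasons(lukewarm), "no summer")
  expect_equal(cal2$label, c("winter", "spring", "winter"))
})

test_that("7-day smoothing suppresses a planted 1-day excursion", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  tmp <- simulate_temperature(dates)
  raw <- tmp$surface
  cal0 <- classify_seasons(smooth_series(raw))
  # plant a 1-day dip to 13 degC mid-summer (below the 15 degC fall onset)
  summer <- cal0[cal0$label == "summer", ][1, ]
  mid <- which(raw$date == summer$start + 40)
  dipped <- raw
  dipped$temperature[mid] <- 13
  cal1 <- classify_seasons(smooth_series(dipped))
  expect_equal(cal1$label, cal0$label)
  expect_equal(cal1$start, cal0$start)
  # without smoothing the dip flips the state machine to fall at the dip day
  cal_raw <- classify_seasons(dipped)
  expect_equal(cal_raw$start[cal_raw$label == "fall"][1], summer$start + 40)
})

test_that("leading winter padding shifts only the first interval start", {
  d0 <- as.Date("2021-01-01")
  tv <- c(rep(4, 60), rep(10, 50), rep(20, 100), rep(12, 30), rep(4, 40))
  s1 <- data.frame(date = d0 + seq_along(tv) - 1, temperature = tv)
  s2 <- data.frame(date = d0 - 30 + seq_len(30 + length(tv)) - 1,
                   temperature = c(rep(4, 30), tv))
  c1 <- classify_seasons(s1); c2 <- classify_seasons(s2)
  expect_equal(c1$label, c2$label)
  expect_equal(c1$start[-1], c2$start[-1])
  expect_equal(c2$start[1], c1$start[1] - 30)
})

test_that("stratification breakpoints: trivial and simulator-truth cases", {
  d0 <- as.Date("2021-01-01")
  s <- data.frame(date = d0 + 0:99, temperature = 10)
  expect_warning(bp <- stratification_breakpoints(s, s), "no stratification")
  expect_true(is.na(bp$onset))

  # planted separation days [30, 70)
  surf <- data.frame(date = d0 + 0:99,
                     temperature = c(rep(5, 30), rep(20, 40), rep(5, 30)))
  expd <- data.frame(date = d0 + 0:99,
                     temperature = c(rep(5, 30), rep(9, 40), rep(5, 30)))
  bp2 <- stratification_breakpoints(surf, expd, delta = 1, k = 5)
  expect_equal(bp2$onset, d0 + 30)
  expect_equal(bp2$breakdown, d0 + 70)
  # delta above the max separation -> no breakpoints
  expect_warning(bp3 <- stratification_breakpoints(surf, expd, delta = 20),
                 "no stratification")
  expect_true(is.na(bp3$onset))
})

test_that("calendar CSV round-trips", {
  cal <- year_calendar()
  path <- withr::local_tempfile(fileext = ".csv")
  write_calendar(cal, path)
  cal2 <- read_calendar(path)
  expect_equal(cal2$start, cal$start)
  expect_equal(cal2$end, cal$end)
  expect_equal(cal2$label, cal$label)
})
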