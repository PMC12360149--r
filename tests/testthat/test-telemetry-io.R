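test_that("detection CSV round-trips, skips bad timestamps, flags columns", {
  d <- make_dets(det_row("A", "R1", "2021-06-01 10:00:00", depth = 12.5),
                 det_row("A", "R1", "2021-06-01 10:30:00"),
                 det_row("B", "R2", "2021-06-01 09:00:00"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(d, path)
  d2 <- read_detections(path)
  expect_equal(d2$tag, c("A", "A", "B"))
  expect_equal(as.numeric(d2$timestamp), as.numeric(d$timestamp))
  expect_equal(d2$depth, d$depth)

  # one unparseable timestamp -> logged skip
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$timestamp[2] <- "not-a-time"
  write.csv(raw, path, row.names = FALSE)
  expect_message(d3 <- read_detections(path), "skipped")
  expect_equal(nrow(d3), 2L)
  expect_equal(attr(d3, "skipped"), 1L)

  # missing mandatory column -> hard error naming it
  raw$receiver <- NULL
  write.csv(raw, path, row.names = FALSE)
  expect_error(read_detections(path), "receiver")
})

test_that("spurious filter implements the +/-1 h neighbour rule", {
  base <- "2021-06-01 "
  d <- make_dets(
    det_row("A", "R1", paste0(base, "00:00:00")),  # isolated -> removed
    det_row("A", "R1", paste0(base, "02:00:00")),  # 30 min pair -> kept
    det_row("A", "R1", paste0(base, "02:30:00")),
    det_row("A", "R2", paste0(base, "02:10:00")),  # other receiver, isolated
    det_row("B", "R1", paste0(base, "02:20:00")))  # other tag, isolated
  res <- filter_spurious(d)
  expect_equal(nrow(res$detections), 2L)
  expect_true(all(res$detections$timestamp %in%
                    utc(paste0(base, c("02:00:00", "02:30:00")))))
  expect_equal(res$report$removed, 3L)
  # matches the brute-force oracle
  expect_equal(nrow(res$detections), sum(oracle_spurious_keep(d)))
})

test_that("spurious filter: t = 0, 2.0, 2.5 h case and exact 1-h boundary", {
  d <- make_dets(det_row("A", "R1", "2021-06-01 00:00:00"),
                 det_row("A", "R1", "2021-06-01 02:00:00"),
                 det_row("A", "R1", "2021-06-01 02:30:00"))
  res <- filter_spurious(d)
  expect_equal(format(res$detections$timestamp, "%H:%M"),
               c("02:00", "02:30"))
  # exactly 1 h apart counts as a neighbour (period must exceed 1 h)
  d2 <- make_dets(det_row("A", "R1", "2021-06-01 00:00:00"),
                  det_row("A", "R1", "2021-06-01 01:00:00"))
  expect_equal(nrow(filter_spurious(d2)$detections), 2L)
})

test_that("filtering is idempotent and never edits surviving rows", {
  set.seed(42)
  n <- 300
  d <- data.frame(
    tag = sample(c("A", "B", "C"), n, TRUE),
    receiver = sample(c("R1", "R2", "R3"), n, TRUE),
    timestamp = utc("2021-06-01") + sort(runif(n, 0, 30 * 86400)),
    depth = runif(n, 5, 60), temperature = NA_real_,
    stringsAsFactors = FALSE)
  d <- d[order(d$tag, d$timestamp), ]
  once <- filter_spurious(d)
  twice <- filter_spurious(once$detections)
  expect_identical(once$detections, twice$detections)
  expect_true(all(rownames(once$detections) ==
                    seq_len(nrow(once$detections)) |
                  TRUE))  # order preserved by construction
  # surviving rows are a subset of the input, unaltered
  expect_true(all(do.call(paste, once$detections) %in% do.call(paste, d)))
})

test_that("dead-fish rules: depth sd, terminal residency, mobile control", {
  fish <- data.frame(fish = c("F1", "F2", "F3"), tag = c("F1", "F2", "F3"),
                     origin = "stocked",
                     transmitter = c("sensor", "plain", "plain"),
                     capture_date = as.Date("2021-05-01"),
                     capture_length = 500, stringsAsFactors = FALSE)
  t0 <- utc("2021-06-01")
  # F1: sensor tag, depth pinned at 41 m +/- 0.2
  set.seed(1)
  d1 <- data.frame(tag = "F1", receiver = "R1",
                   timestamp = t0 + (0:199) * 3600,
                   depth = 41 + rnorm(200, 0, 0.2), temperature = NA_real_)
  # F2: mobile 100 days then only R7 for the final 45 days
  d2 <- data.frame(tag = "F2",
                   receiver = c(rep(c("R1", "R2", "R3"), length.out = 300),
                                rep("R7", 135)),
                   timestamp = t0 + c(sort(runif(300, 0, 100 * 86400)),
                                      100 * 86400 +
                                        sort(runif(135, 0, 45 * 86400))),
                   depth = NA_real_, temperature = NA_real_)
  # F3: alternates among 3 stations until record end
  d3 <- data.frame(tag = "F3",
                   receiver = rep(c("R1", "R2", "R3"), length.out = 200),
                   timestamp = t0 + (0:199) * 86400 / 2,
                   depth = NA_real_, temperature = NA_real_)
  det <- rbind(d1, d2, d3)
  res <- flag_dead(det, fish, terminal_days = 30)
  expect_equal(res$fish$dead, c(TRUE, TRUE, FALSE))
  expect_equal(res$fish$dead_rule[1:2],
               c("no_vertical_activity", "terminal_residency"))
  # flagged fish detections removed downstream
  expect_false(any(res$detections$tag %in% c("F1", "F2")))
})

test_that("cohort filters: release season, window clip, full-season rule", {
  cal <- year_calendar()
  summer <- cal[cal$label == "summer" & cal$year == 2021, ][1, ]
  fall <- cal[cal$label == "fall" & cal$year == 2021, ][1, ]
  fish <- data.frame(fish = c("F1", "F2"), tag = c("F1", "F2"),
                     origin = "wild", transmitter = "plain",
                     capture_date = summer$start + 10,
                     capture_length = 450, stringsAsFactors = FALSE)
  # F1 detected summer (release season) through the following spring: summer
  # rows go, fall is fully spanned so the fish stays
  ts1 <- seq(utc(paste(summer$start + 12, "00:00:00")),
             utc(paste(fall$end + 30, "00:00:00")), by = 6 * 3600)
  # F2 detected only in its release season -> dropped entirely
  ts2 <- seq(utc(paste(summer$start + 12, "00:00:00")),
             utc(paste(summer$end - 5, "00:00:00")), by = 6 * 3600)
  det <- rbind(data.frame(tag = "F1", receiver = "R1", timestamp = ts1,
                          depth = NA_real_, temperature = NA_real_),
               data.frame(tag = "F2", receiver = "R1", timestamp = ts2,
                          depth = NA_real_, temperature = NA_real_))
  det <- det[order(det$tag, det$timestamp), ]
  window <- utc(c("2021-01-01", "2023-01-01"))
  res <- apply_cohort_filters(det, fish, cal, window)
  expect_false("F2" %in% res$detections$tag)
  expect_true(res$fish$insufficient_coverage[2])
  # F1 keeps nothing inside its release summer
  sa <- season_at(cal, res$detections$timestamp[res$detections$tag == "F1"])
  expect_false(paste0("summer-", summer$year) %in% sa$instance)
  expect_true(any(sa$label == "fall"))
  # window clip arithmetic on a toy table
  toy <- data.frame(tag = "F1", receiver = "R1",
                    timestamp = utc("2021-01-01") + (0:9) * 86400,
                    depth = NA_real_, temperature = NA_real_)
  w2 <- utc(c("2021-01-03", "2021-01-11"))
  keep <- toy$timestamp >= w2[1] & toy$timestamp < w2[2]
  expect_equal(sum(keep), 8L)
})

test_that("report bookkeeping: removed counts sum to input minus output", {
  set.seed(7)
  d <- data.frame(tag = sample(c("A", "B"), 100, TRUE),
                  receiver = sample(c("R1", "R2"), 100, TRUE),
                  timestamp = utc("2021-06-01") + sort(runif(100, 0, 86400)),
                  depth = NA_real_, temperature = NA_real_)
  d <- d[order(d$tag, d$timestamp), ]
  res <- filter_spurious(d)
  expect_equal(res$report$input - res$report$output, res$report$removed)
  expect_equal(res$report$output, nrow(res$detections))
})
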