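# Depth-day protocol: a fish-day-region is analysed only when it has more
# than 20 depth-bearing detections; each eligible day is summarized from a
# fixed 20-value random subsample so daily standard deviations are not
# biased by unequal sample sizes.

#' Eligible depth days
#'
#' A (fish, date, region) triple is retained when it has strictly more than
#' `min_detections` detections carrying depth values (so 20 is excluded, 21
#' included at the default).
#'
#' @param detections detections joined with receiver `region`.
#' @param min_detections exclusive threshold (default 20).
#' @return data.frame `fish`, `date`, `region`, `n_depth`.
#' @export
eligible_depth_days <- function(detections, min_detections = 20) {
  d <- detections[!is.na(detections$depth), , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(fish = character(), date = as.Date(character()),
                      region = character(), n_depth = integer()))
  d$date <- as.Date(d$timestamp, tz = "UTC")
  counts <- aggregate(depth ~ tag + date + region, data = d, FUN = length)
  names(counts) <- c("fish", "date", "region", "n_depth")
  out <- counts[counts$n_depth > min_detections, , drop = FALSE]
  out <- out[order(out$fish, out$date, out$region), ]
  rownames(out) <- NULL
  out
}

#' Daily depth summaries from fixed-size subsamples
#'
#' For every eligible (fish, date, region), draws `size` depth values
#' uniformly without replacement, and records the subsample mean ("average
#' daily depth"), its sample standard deviation ("vertical activity",
#' n - 1 denominator), and the station-depth covariate. The covariate is the
#' mean station depth over the contributing detections
#' (`station_weighting = "detections"`, each drawn value carrying its
#' station's depth) or over the distinct stations involved (`"distinct"`).
#' Each row's draw uses a sub-seed derived from `seed` and the row key, and
#' the sub-seed is recorded for reproducibility.
#'
#' @param detections depth-bearing detections joined with receiver `region`
#'   and `station_depth`.
#' @param eligible table from [eligible_depth_days()]; an error is raised if
#'   a requested day is not eligible.
#' @param size subsample size (default 20).
#' @param seed integer master seed.
#' @param station_weighting "detections" (default) or "distinct".
#' @return DepthDaily data.frame: `fish`, `date`, `region`, `mean_depth`,
#'   `sd_depth`, `station_depth`, `seed`.
#' @export
subsample_depths <- function(detections, eligible, size = 20, seed = 1L,
                             station_weighting = c("detections",
                                                   "distinct")) {
  station_weighting <- match.arg(station_weighting)
  d <- detections[!is.na(detections$depth), , drop = FALSE]
  d$date <- as.Date(d$timestamp, tz = "UTC")
  if (is.null(d$station_depth) || anyNA(d$station_depth))
    stop("station depths missing; join receiver metadata first",
         call. = FALSE)
  rows <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    e <- eligible[i, ]
    ix <- which(d$tag == e$fish & d$date == e$date & d$region == e$region)
    if (length(ix) <= size)
      stop("day not eligible: ", e$fish, " ", e$date, " ", e$region,
           " has ", length(ix), " depth detections", call. = FALSE)
    row_seed <- sub_seed(seed, i + 271828L)
    set.seed(row_seed)
    pick <- sample(ix, size)
    dep <- d$depth[pick]
    sdep <- if (station_weighting == "detections")
      mean(d$station_depth[pick])
    else mean(d$station_depth[pick][!duplicated(d$station[pick])])
    rows[[i]] <- data.frame(fish = e$fish, date = e$date, region = e$region,
                            mean_depth = mean(dep), sd_depth = sd(dep),
                            station_depth = sdep, seed = row_seed,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fish = character(), date = as.Date(character()),
                      region = character(), mean_depth = numeric(),
                      sd_depth = numeric(), station_depth = numeric(),
                      seed = integer())
  rownames(out) <- NULL
  out
}

#' Station-depth covariate of a detection subset
#'
#' Mean station depth over contributing detections (detection-weighted) or
#' over distinct stations.
#'
#' @param station_depths station depth (m) of each contributing detection.
#' @param stations station ids parallel to `station_depths` (needed for
#'   `"distinct"`).
#' @param weighting "detections" or "distinct".
#' @return metres.
#' @export
station_depth_covariate <- function(station_depths, stations = NULL,
                                    weighting = c("detections", "distinct")) {
  weighting <- match.arg(weighting)
  if (anyNA(station_depths)) stop("missing station depth", call. = FALSE)
  if (weighting == "detections") return(mean(station_depths))
  stopifnot(!is.null(stations))
  mean(station_depths[!duplicated(stations)])
}
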