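# Land-avoiding hourly path interpolation and region-use metrics. Routes
# between stations are straight lines where the segment stays in water and
# shortest paths over an 8-connected water-raster graph otherwise.

#' Build a traversal graph over the water
#'
#' Square raster at `resolution` metres over the lake bounding box; cells
#' whose centres are in water become vertices, connected to their 8
#' neighbours with Euclidean centre-to-centre edge weights. Deterministic for
#' a given lake and resolution.
#'
#' @param lake a `lake_geometry`.
#' @param resolution cell size (m, default 250); must be smaller than the
#'   narrowest passage that should stay traversable.
#' @return a `water_graph`: list with `graph` (igraph), `cells` (data.frame
#'   `node`, `x`, `y`), `resolution`.
#' @export
water_graph <- function(lake, resolution = 250) {
  stopifnot(resolution > 0)
  xs <- seq(lake$bbox["xmin"] + resolution / 2, lake$bbox["xmax"],
            by = resolution)
  ys <- seq(lake$bbox["ymin"] + resolution / 2, lake$bbox["ymax"],
            by = resolution)
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  g$x <- xs[g$ix]; g$y <- ys[g$iy]
  wet <- is_water(lake, cbind(g$x, g$y))
  g <- g[wet, , drop = FALSE]
  g$node <- seq_len(nrow(g))
  idx <- matrix(NA_integer_, nx, ny)
  idx[cbind(g$ix, g$iy)] <- g$node

  nbr <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))  # undirected: half-star
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(nbr))) {
    jx <- g$ix + nbr[k, 1]; jy <- g$iy + nbr[k, 2]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    to <- rep(NA_integer_, nrow(g))
    to[ok] <- idx[cbind(jx[ok], jy[ok])]
    ok <- ok & !is.na(to)
    ef <- c(ef, g$node[ok]); et <- c(et, to[ok])
    ew <- c(ew, rep(resolution * sqrt(sum(nbr[k, ]^2)), sum(ok)))
  }
  gr <- igraph::make_empty_graph(n = nrow(g), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(ef, et))
  igraph::E(gr)$weight <- ew
  structure(list(graph = gr,
                 cells = data.frame(node = g$node, x = g$x, y = g$y),
                 resolution = resolution),
            class = "water_graph")
}

nearest_node <- function(wg, pt) {
  which.min((wg$cells$x - pt[1])^2 + (wg$cells$y - pt[2])^2)
}

#' Shortest in-water route between two points
#'
#' Straight segment when it stays in water (checked at half-resolution
#' sampling); otherwise the graph shortest path between nearest water nodes,
#' with the exact endpoints appended. Errors if the endpoints sit in
#' disconnected water components.
#'
#' @param lake a `lake_geometry`.
#' @param wg a [water_graph()].
#' @param from,to length-2 numeric points (m).
#' @return two-column matrix of route vertices from `from` to `to`.
#' @export
water_route <- function(lake, wg, from, to) {
  if (segment_in_water(lake, from, to, wg$resolution / 2))
    return(rbind(from, to))
  a <- nearest_node(wg, from); b <- nearest_node(wg, to)
  sp <- suppressWarnings(
    igraph::shortest_paths(wg$graph, a, b, output = "vpath"))
  v <- as.integer(sp$vpath[[1]])
  if (length(v) == 0L)
    stop("receivers lie in disconnected water components (nodes ", a,
         ", ", b, ")", call. = FALSE)
  mid <- cbind(wg$cells$x[v], wg$cells$y[v])
  unname(rbind(from, mid, to))
}

segment_in_water <- function(lake, from, to, step) {
  len <- sqrt(sum((to - from)^2))
  if (len == 0) return(is_water(lake, matrix(from, ncol = 2)))
  f <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
  pts <- cbind(from[1] + f * (to[1] - from[1]),
               from[2] + f * (to[2] - from[2]))
  all(is_water(lake, pts))
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

point_along <- function(p, dist) {
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cs <- c(0, cumsum(seg))
  dist <- pmin(pmax(dist, 0), cs[length(cs)])
  i <- findInterval(dist, cs, rightmost.closed = TRUE)
  i <- pmin(i, nrow(p) - 1L)
  f <- ifelse(seg[i] > 0, (dist - cs[i]) / seg[i], 0)
  cbind(p[i, 1] + f * (p[i + 1L, 1] - p[i, 1]),
        p[i, 2] + f * (p[i + 1L, 2] - p[i, 2]))
}

#' Interpolate an hourly land-avoiding path from detections
#'
#' Positions are emitted at whole clock hours between a fish's first and last
#' detection. Between consecutive detections at different stations the fish
#' moves along the in-water route (straight where possible, water-graph
#' shortest path otherwise) at a position proportional to elapsed time;
#' consecutive detections at one station give stationary points. All gaps are
#' interpolated regardless of length; each point records the enclosing gap in
#' hours so downstream users can weigh long gaps.
#'
#' @param detections one fish's detections, joined with receiver positions
#'   (columns `x`, `y`, `station`; see [join_receivers()]).
#' @param lake a `lake_geometry`.
#' @param wg a [water_graph()].
#' @return data.frame of PathPoints: `fish`, `timestamp`, `x`, `y`, `region`,
#'   `interpolated`, `gap_h`.
#' @export
interpolate_path <- function(detections, lake, wg) {
  stopifnot(nrow(detections) >= 2L,
            all(c("x", "y") %in% names(detections)))
  d <- detections[order(detections$timestamp), , drop = FALSE]
  fish <- d$tag[1]
  t0 <- ceiling_hour(d$timestamp[1])
  t1 <- floor_hour(d$timestamp[nrow(d)])
  if (t1 < t0)
    return(data.frame(fish = character(), timestamp = as.POSIXct(character()),
                      x = numeric(), y = numeric(), region = character(),
                      interpolated = logical(), gap_h = numeric()))
  hours <- seq(t0, t1, by = 3600)
  tt <- as.numeric(d$timestamp)
  hh <- as.numeric(hours)
  i <- findInterval(hh, tt)
  i <- pmin(pmax(i, 1L), nrow(d) - 1L)
  px <- numeric(length(hours)); py <- numeric(length(hours))
  interp <- logical(length(hours)); gap <- numeric(length(hours))
  route_cache <- new.env(parent = emptyenv())
  for (k in seq_along(hours)) {
    a <- i[k]; b <- a + 1L
    same <- d$station[a] == d$station[b]
    f <- if (tt[b] > tt[a]) (hh[k] - tt[a]) / (tt[b] - tt[a]) else 0
    f <- min(max(f, 0), 1)
    if (same || f == 0) {
      px[k] <- d$x[a]; py[k] <- d$y[a]
    } else if (f == 1) {
      px[k] <- d$x[b]; py[k] <- d$y[b]
    } else {
      key <- paste(d$station[a], d$station[b])
      rt <- route_cache[[key]]
      if (is.null(rt)) {
        rt <- water_route(lake, wg, c(d$x[a], d$y[a]), c(d$x[b], d$y[b]))
        route_cache[[key]] <- rt
      }
      p <- point_along(rt, f * polyline_length(rt))
      px[k] <- p[1]; py[k] <- p[2]
    }
    interp[k] <- !(hh[k] %in% tt)
    gap[k] <- (tt[b] - tt[a]) / 3600
  }
  reg <- point_region(lake, cbind(px, py))
  # a point exactly on a boundary keeps the previous point's region
  for (k in seq_along(reg))
    if (is.na(reg[k]) && k > 1L) reg[k] <- reg[k - 1L]
  data.frame(fish = fish, timestamp = hours, x = px, y = py, region = reg,
             interpolated = interp, gap_h = gap, stringsAsFactors = FALSE)
}

ceiling_hour <- function(t) as.POSIXct(ceiling(as.numeric(t) / 3600) * 3600,
                                       origin = "1970-01-01", tz = "UTC")
floor_hour <- function(t) as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
                                     origin = "1970-01-01", tz = "UTC")

#' Regional occupancy per fish-season
#'
#' Proportion of position-hours spent in each region within each season
#' instance, the number of distinct regions touched, and the maximum
#' occupancy. Proportions are over hours with estimated positions, not
#' calendar hours.
#'
#' @param path PathPoint data.frame (one or many fish).
#' @param calendar a `season_calendar`.
#' @return data.frame `fish`, `instance`, `season`, `year`, `region_count`,
#'   `max_occupancy`, `top_region`, `days_with_positions`, plus a long
#'   `proportions` attribute (`fish`, `instance`, `region`, `proportion`).
#' @export
occupancy <- function(path, calendar) {
  sa <- season_at(calendar, path$timestamp)
  path$instance <- sa$instance
  path <- path[!is.na(path$instance) & !is.na(path$region), , drop = FALSE]
  if (nrow(path) == 0L)
    return(data.frame(fish = character(), instance = character(),
                      season = character(), year = integer(),
                      region_count = integer(), max_occupancy = numeric(),
                      top_region = character(),
                      days_with_positions = integer()))
  key <- interaction(path$fish, path$instance, drop = TRUE)
  props <- list(); rows <- list()
  for (ix in split(seq_len(nrow(path)), key)) {
    p <- path[ix, ]
    tab <- table(p$region)
    pr <- as.numeric(tab) / sum(tab)
    props[[length(props) + 1L]] <- data.frame(
      fish = p$fish[1], instance = p$instance[1], region = names(tab),
      proportion = pr, stringsAsFactors = FALSE)
    inst <- strsplit(p$instance[1], "-")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      fish = p$fish[1], instance = p$instance[1],
      season = inst[1], year = as.integer(inst[2]),
      region_count = length(tab), max_occupancy = max(pr),
      top_region = names(tab)[which.max(pr)],
      days_with_positions = length(unique(as.Date(p$timestamp, tz = "UTC"))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "proportions") <- do.call(rbind, props)
  out
}

#' Compress proportions into the open unit interval for beta models
#'
#' `y' = (y * (n - 1) + 0.5) / n`: order-preserving, shifts the boundaries by
#' about 0.001 at n = 500, and fixes 0.5.
#'
#' @param y values in \[0, 1\].
#' @param n sample size (>= 2).
#' @return values strictly inside (0, 1).
#' @export
compress_for_beta <- function(y, n) {
  stopifnot(n >= 2, all(y >= 0), all(y <= 1))
  (y * (n - 1) + 0.5) / n
}
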