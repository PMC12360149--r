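# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the code paths they check (brute-force scans, textbook Dijkstra, flood
# fill) so recovery tests compare two independent routes to the same answer.

utc <- function(x) as.POSIXct(x, tz = "UTC")

toy_lake <- function(width = 8000, height = 8000, hex_spacing = 1000) {
  make_lake(list(A = c(0, width, 0, height)), hex_spacing = hex_spacing)
}

two_region_lake <- function(side = 4000, hex_spacing = 1000) {
  make_lake(list(A = c(0, side, 0, side),
                 B = c(side, 2 * side, 0, side)),
            hex_spacing = hex_spacing)
}

# annual calendar built once for reuse
year_calendar <- function(year = 2021) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year + 1)), by = "day")
  classify_seasons(smooth_series(simulate_temperature(dates)$surface))
}

# detections data.frame builder
det_row <- function(tag, receiver, ts, depth = NA_real_,
                    temperature = NA_real_) {
  data.frame(tag = tag, receiver = receiver, timestamp = utc(ts),
             depth = depth, temperature = temperature,
             stringsAsFactors = FALSE)
}

make_dets <- function(...) {
  d <- do.call(rbind, list(...))
  d[order(d$tag, d$timestamp), ]
}

# --- independent oracles ------------------------------------------------

# brute-force spurious rule: keep iff another same-tag-same-receiver
# detection lies within +/- 1 h
oracle_spurious_keep <- function(det) {
  n <- nrow(det)
  keep <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (det$tag[i] == det$tag[j] && det$receiver[i] == det$receiver[j] &&
          abs(as.numeric(det$timestamp[i]) -
              as.numeric(det$timestamp[j])) <= 3600) {
        keep[i] <- TRUE; break
      }
    }
  }
  keep
}

# textbook Dijkstra on an 8-connected water raster, independent of igraph
oracle_grid_dijkstra <- function(lake, resolution, from, to) {
  xs <- seq(lake$bbox["xmin"] + resolution / 2, lake$bbox["xmax"],
            by = resolution)
  ys <- seq(lake$bbox["ymin"] + resolution / 2, lake$bbox["ymax"],
            by = resolution)
  g <- expand.grid(x = xs, y = ys)
  wet <- is_water(lake, as.matrix(g))
  g <- g[wet, ]
  n <- nrow(g)
  src <- which.min((g$x - from[1])^2 + (g$y - from[2])^2)
  dst <- which.min((g$x - to[1])^2 + (g$y - to[2])^2)
  dist <- rep(Inf, n); dist[src] <- 0
  done <- logical(n)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || u == dst) break
    done[u] <- TRUE
    nb <- which(!done & abs(g$x - g$x[u]) <= resolution * 1.01 &
                  abs(g$y - g$y[u]) <= resolution * 1.01)
    w <- sqrt((g$x[nb] - g$x[u])^2 + (g$y[nb] - g$y[u])^2)
    upd <- dist[u] + w < dist[nb]
    dist[nb[upd]] <- dist[u] + w[upd]
  }
  dist[dst]
}

# flood fill over the water mask (connectivity oracle)
oracle_flood_fill_connected <- function(lake, resolution = 500) {
  xs <- seq(lake$bbox["xmin"] + resolution / 2, lake$bbox["xmax"],
            by = resolution)
  ys <- seq(lake$bbox["ymin"] + resolution / 2, lake$bbox["ymax"],
            by = resolution)
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  wet <- matrix(is_water(lake, cbind(xs[g$ix], ys[g$iy])), nx, ny)
  seen <- matrix(FALSE, nx, ny)
  start <- which(wet, arr.ind = TRUE)[1, ]
  stack <- list(start)
  seen[start[1], start[2]] <- TRUE
  while (length(stack)) {
    c0 <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dx in -1:1) for (dy in -1:1) {
      i <- c0[1] + dx; j <- c0[2] + dy
      if (i >= 1 && i <= nx && j >= 1 && j <= ny && wet[i, j] &&
          !seen[i, j]) {
        seen[i, j] <- TRUE
        stack[[length(stack) + 1L]] <- c(i, j)
      }
    }
  }
  sum(seen) == sum(wet)
}
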