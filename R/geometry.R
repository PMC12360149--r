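# Planar lake geometry: region polygons, land mask, hexagonal grid.
# Coordinates are metres in a local projection; polygons are plain two-column
# matrices (x, y), vertex rings open (first vertex not repeated).

#' Test points against a polygon
#'
#' Ray-crossing point-in-polygon via [mgcv::in.out()]. Points exactly on the
#' boundary follow `mgcv`'s convention; callers needing deterministic
#' tie-breaks handle boundaries themselves.
#'
#' @param pts two-column matrix of (x, y) points, metres.
#' @param poly two-column matrix of polygon vertices (open ring).
#' @return logical vector, `TRUE` where the point is inside.
#' @keywords internal
point_in_poly <- function(pts, poly) {
  pts <- as_xy_matrix(pts)
  if (nrow(pts) == 0L) return(logical(0))
  mgcv::in.out(rbind(poly, poly[1L, , drop = FALSE]), pts)
}

as_xy_matrix <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y")])
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  storage.mode(pts) <- "double"
  pts
}

#' Region label at planar points
#'
#' @param lake a `lake_geometry` object.
#' @param pts two-column matrix of points (metres).
#' @return character vector of region labels; `NA` for points on land or
#'   outside every region.
#' @export
point_region <- function(lake, pts) {
  stopifnot(inherits(lake, "lake_geometry"))
  pts <- as_xy_matrix(pts)
  out <- rep(NA_character_, nrow(pts))
  for (nm in names(lake$regions)) {
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- point_in_poly(pts[todo, , drop = FALSE], lake$regions[[nm]])
    out[which(todo)[hit]] <- nm
  }
  if (length(lake$land)) {
    for (lp in lake$land) {
      inland <- point_in_poly(pts, lp)
      out[inland] <- NA_character_
    }
  }
  out
}

#' Is a point in water?
#'
#' Water means inside some region polygon and outside every land polygon.
#'
#' @inheritParams point_region
#' @return logical vector.
#' @export
is_water <- function(lake, pts) !is.na(point_region(lake, pts))

#' Depth of the lake bottom at planar points
#'
#' Per-region constant depth (metres); the generator does not model finer
#' bathymetry.
#'
#' @inheritParams point_region
#' @return numeric vector of depths (m); `NA` on land.
#' @export
lake_depth_at <- function(lake, pts) {
  reg <- point_region(lake, pts)
  unname(lake$region_depth[reg])
}

# Flat-top hexagon axial coordinates. Centroid spacing d between any pair of
# adjacent cells implies circumradius R = d / sqrt(3).
hex_axial_to_xy <- function(q, r, R, origin) {
  cbind(x = origin[1] + R * 1.5 * q,
        y = origin[2] + R * sqrt(3) * (r + q / 2))
}

hex_xy_to_axial_frac <- function(pts, R, origin) {
  x <- pts[, 1] - origin[1]
  y <- pts[, 2] - origin[2]
  cbind(q = (2 / 3) * x / R,
        r = (-1 / 3) * x / R + (sqrt(3) / 3) * y / R)
}

# Exact cube rounding of fractional axial coordinates.
hex_round <- function(qr) {
  q <- qr[, 1]; r <- qr[, 2]; s <- -q - r
  rq <- round(q); rr <- round(r); rs <- round(s)
  dq <- abs(rq - q); dr <- abs(rr - r); ds <- abs(rs - s)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  rq[fix_q] <- -rr[fix_q] - rs[fix_q]
  rr[fix_r] <- -rq[fix_r] - rs[fix_r]
  cbind(q = rq, r = rr)
}

#' Vertices of a flat-top hexagon
#' @keywords internal
hex_vertices <- function(cx, cy, R) {
  ang <- (0:5) * pi / 3
  cbind(x = cx + R * cos(ang), y = cy + R * sin(ang))
}

#' Build a synthetic lake
#'
#' Constructs planar lake geometry: named region polygons, an optional land
#' mask (islands), a per-region bottom depth, and a hexagonal grid (flat-top
#' hexagons, `hex_spacing` metres between adjacent centroids) covering all
#' water. Cell ids are assigned deterministically in (y, x) centroid order so
#' the same configuration always yields byte-identical geometry.
#'
#' @param regions named list of polygon vertex matrices (metres), pairwise
#'   disjoint, or of length-4 vectors `c(xmin, xmax, ymin, ymax)` for
#'   rectangles.
#' @param land optional list of island polygons.
#' @param hex_spacing centroid spacing of the hex grid in metres (default
#'   1000, i.e. the 1-km analysis grid).
#' @param region_depth named numeric vector of bottom depths (m) per region;
#'   recycled from `default_depth` when missing.
#' @param default_depth bottom depth (m) for regions without an entry.
#' @return a `lake_geometry` object: list with `regions`, `land`, `hex`
#'   (data.frame `cell`, `cx`, `cy`, `region`), `hex_R`, `hex_spacing`,
#'   `hex_origin`, `bbox`, `region_depth`.
#' @examples
#' lake <- make_lake(list(main = c(0, 10000, 0, 40000)))
#' nrow(lake$hex) > 0
#' @export
make_lake <- function(regions, land = list(), hex_spacing = 1000,
                      region_depth = NULL, default_depth = 100) {
  stopifnot(length(regions) >= 1, !is.null(names(regions)),
            all(nzchar(names(regions))))
  regions <- lapply(regions, function(rg) {
    if (!is.matrix(rg) && length(rg) == 4L) {
      rg <- cbind(x = c(rg[1], rg[2], rg[2], rg[1]),
                  y = c(rg[3], rg[3], rg[4], rg[4]))
    }
    rg <- as_xy_matrix(rg)
    if (abs(ring_area(rg)) <= 0)
      stop("degenerate region polygon: zero area", call. = FALSE)
    rg
  })
  land <- lapply(land, as_xy_matrix)
  allv <- do.call(rbind, regions)
  bbox <- c(xmin = min(allv[, 1]), xmax = max(allv[, 1]),
            ymin = min(allv[, 2]), ymax = max(allv[, 2]))
  if (bbox["xmax"] <= bbox["xmin"] || bbox["ymax"] <= bbox["ymin"])
    stop("degenerate extent: zero area", call. = FALSE)

  depth <- setNames(rep(default_depth, length(regions)), names(regions))
  if (!is.null(region_depth)) depth[names(region_depth)] <- region_depth

  R <- hex_spacing / sqrt(3)
  origin <- c(bbox[["xmin"]], bbox[["ymin"]])
  lake <- structure(list(regions = regions, land = land, hex = NULL,
                         hex_R = R, hex_spacing = hex_spacing,
                         hex_origin = origin, bbox = bbox,
                         region_depth = depth),
                    class = "lake_geometry")

  # Candidate axial range generous enough to cover the bbox plus one ring.
  qmax <- ceiling((bbox[["xmax"]] - bbox[["xmin"]]) / (1.5 * R)) + 1L
  rmax <- ceiling((bbox[["ymax"]] - bbox[["ymin"]]) / (sqrt(3) * R)) + 1L
  grid <- expand.grid(q = -1:qmax, r = seq(-qmax, rmax + 1L))
  ctr <- hex_axial_to_xy(grid$q, grid$r, R, origin)
  # Keep cells that touch water at centroid or any vertex (grid covers water).
  keep_reg <- point_region(lake, ctr)
  keep <- !is.na(keep_reg)
  ang <- (0:5) * pi / 3
  for (k in seq_along(ang)) {
    vx <- cbind(ctr[, 1] + R * cos(ang[k]), ctr[, 2] + R * sin(ang[k]))
    vreg <- point_region(lake, vx)
    fill <- !keep & !is.na(vreg)
    keep_reg[fill] <- vreg[fill]
    keep <- keep | fill
  }
  hx <- data.frame(q = grid$q[keep], r = grid$r[keep],
                   cx = ctr[keep, 1], cy = ctr[keep, 2],
                   region = keep_reg[keep], stringsAsFactors = FALSE)
  hx <- hx[order(hx$cy, hx$cx), ]
  hx$cell <- seq_len(nrow(hx))
  rownames(hx) <- NULL
  lake$hex <- hx[, c("cell", "q", "r", "cx", "cy", "region")]
  lake
}

ring_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

#' Assign planar points to hexagonal grid cells
#'
#' Exact cube-coordinate rounding; a point equidistant from several centroids
#' (a shared edge or corner) is assigned deterministically to the lowest cell
#' id among the nearest.
#'
#' @param lake a `lake_geometry` with a hex grid.
#' @param pts two-column matrix of points (metres).
#' @return integer vector of cell ids; error if a point falls outside the
#'   grid (the grid must cover all water).
#' @export
hex_cell_at <- function(lake, pts) {
  stopifnot(inherits(lake, "lake_geometry"))
  pts <- as_xy_matrix(pts)
  hx <- lake$hex
  key <- paste(hx$q, hx$r)
  idx <- setNames(hx$cell, key)
  ax <- hex_round(hex_xy_to_axial_frac(pts, lake$hex_R, lake$hex_origin))
  cell <- unname(idx[paste(ax[, 1], ax[, 2])])
  if (anyNA(cell))
    stop("point outside hex grid: the grid must cover all water",
         call. = FALSE)
  # Boundary tie-break: among the assigned cell and its 6 axial neighbours,
  # pick the lowest id within 1e-9 m of the minimum centroid distance.
  nb <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  d_best <- sqrt((pts[, 1] - hx$cx[cell])^2 + (pts[, 2] - hx$cy[cell])^2)
  best <- cell
  for (k in 2:nrow(nb)) {
    cand <- unname(idx[paste(ax[, 1] + nb[k, 1], ax[, 2] + nb[k, 2])])
    ok <- !is.na(cand)
    if (!any(ok)) next
    d <- rep(Inf, length(cell))
    d[ok] <- sqrt((pts[ok, 1] - hx$cx[cand[ok]])^2 +
                  (pts[ok, 2] - hx$cy[cand[ok]])^2)
    swap <- ok & ((d < d_best - 1e-9) | (abs(d - d_best) <= 1e-9 & cand < best))
    best[swap] <- cand[swap]
    d_best[swap] <- d[swap]
  }
  best
}

#' Write lake geometry to GeoJSON
#'
#' Region polygons carry a `region` property; land polygons carry
#' `land: true`. Coordinates are planar metres (the projection is local, not
#' geographic); grid parameters travel in the top-level `properties`.
#'
#' @param lake a `lake_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lake_geojson <- function(lake, path) {
  feat <- c(
    lapply(names(lake$regions), function(nm) {
      ring <- lake$regions[[nm]]
      list(type = "Feature",
           properties = list(region = nm,
                             depth_m = unname(lake$region_depth[nm])),
           geometry = list(type = "Polygon",
                           coordinates = list(close_ring(ring))))
    }),
    lapply(lake$land, function(ring) {
      list(type = "Feature", properties = list(land = TRUE),
           geometry = list(type = "Polygon",
                           coordinates = list(close_ring(ring))))
    })
  )
  obj <- list(type = "FeatureCollection",
              properties = list(hex_spacing = lake$hex_spacing,
                                projection = "local planar metres"),
              features = feat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(ring) {
  ring <- rbind(ring, ring[1L, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Read lake geometry from GeoJSON
#'
#' Inverse of [write_lake_geojson()]; the hex grid is rebuilt
#' deterministically from the stored spacing.
#'
#' @param path GeoJSON file written by [write_lake_geojson()].
#' @return a `lake_geometry`.
#' @export
read_lake_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  regions <- list(); land <- list(); depth <- c()
  for (f in obj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    colnames(ring) <- c("x", "y")
    if (isTRUE(f$properties$land)) {
      land[[length(land) + 1L]] <- ring
    } else {
      regions[[f$properties$region]] <- ring
      depth[f$properties$region] <- f$properties$depth_m
    }
  }
  make_lake(regions, land = land,
            hex_spacing = obj$properties$hex_spacing,
            region_depth = depth)
}
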