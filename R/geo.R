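# Minimal planar polygon geometry for range-edge distances.
#
# A species range is a list of parts; each part is a list with
#   $outer : closed ring, matrix with columns (lon, lat) or planar (x, y) km
#   $holes : list of closed rings (gaps inside the part)
# Rings need not repeat the first vertex; they are closed implicitly.

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3) stop("a ring needs at least 3 vertices")
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  unname(ring)
}

# Even-odd ray casting; returns TRUE for points strictly inside (boundary
# points count as inside).
.point_in_ring <- function(pt, ring) {
  ring <- .close_ring(ring)
  x <- pt[1]; y <- pt[2]
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

# Distance from a point to the segments of a ring (planar metric).
.dist_to_ring <- function(pt, ring) {
  ring <- .close_ring(ring)
  n <- nrow(ring) - 1L
  a <- ring[seq_len(n), , drop = FALSE]
  b <- ring[seq_len(n) + 1L, , drop = FALSE]
  ab <- b - a
  ap <- cbind(pt[1] - a[, 1], pt[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, pmin(1, pmax(0, rowSums(ap * ab) / len2)), 0)
  proj <- a + ab * t
  min(sqrt((pt[1] - proj[, 1])^2 + (pt[2] - proj[, 2])^2))
}

# Project lon/lat coordinates to local equirectangular km about `origin`
# (lon0, lat0).  Error is negligible at the ~10 km scales the buffers use.
.project_local <- function(coords, origin) {
  coords <- as.matrix(coords)
  cbind((coords[, 1] - origin[1]) * .KM_PER_DEG_LON * cos(origin[2] * pi / 180),
        (coords[, 2] - origin[2]) * .KM_PER_DEG_LAT)
}

.project_part <- function(part, origin, crs) {
  if (crs == "planar") return(part)
  list(outer = .project_local(part$outer, origin),
       holes = lapply(part$holes, .project_local, origin = origin))
}

# Depth of grid points inside a hole ring that survive erosion by `r` km;
# returns the surviving grid points (matrix, possibly 0 rows).
.eroded_hole_points <- function(hole, r) {
  hole <- .close_ring(hole)
  step <- r / 8
  xs <- seq(min(hole[, 1]), max(hole[, 1]), by = step)
  ys <- seq(min(hole[, 2]), max(hole[, 2]), by = step)
  if (!length(xs) || !length(ys)) return(matrix(numeric(0), ncol = 2))
  grid <- as.matrix(expand.grid(xs, ys))
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    keep[i] <- .point_in_ring(p, hole) && .dist_to_ring(p, hole) >= r
  }
  grid[keep, , drop = FALSE]
}

#' Distance from a location to the species range edge, closing small gaps
#'
#' Shortest distance (km) from a point to the edge of a range polygon,
#' after morphologically closing interior gaps narrower than `buffer_km`
#' (dilating the range by `buffer_km`, measuring distance to the dilated
#' edge, and subtracting `buffer_km` — so small lakes and rivers inside the
#' range do not count as edge).  Points outside the range are assigned a
#' distance of zero.
#'
#' For the outer boundary the dilation cancels exactly and the plain
#' point-to-boundary distance is used.  For each gap (hole), the eroded gap
#' (the set of points deeper than `buffer_km` inside it) is approximated on
#' a grid of spacing `buffer_km / 8`; a gap whose erosion is empty — e.g.
#' an 8-km lake under the default 10-km buffer — vanishes entirely.
#'
#' @param point Numeric length-2: (lon, lat) or planar (x, y) in km.
#' @param range_polygon A list of parts (see Details) or a single part; each
#'   part is `list(outer = ring, holes = list(...))` with rings as two-column
#'   coordinate matrices.
#' @param buffer_km Closing radius in km (default 10).
#' @param crs `"lonlat"` (default; a local equirectangular projection about
#'   the point is applied) or `"planar"` (coordinates already in km).
#' @return Distance in km (0 for points outside the range).
#' @export
#' @examples
#' sq <- list(outer = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)), holes = list())
#' distance_to_edge(c(50, 50), sq, crs = "planar")
distance_to_edge <- function(point, range_polygon, buffer_km = 10,
                             crs = c("lonlat", "planar")) {
  crs <- match.arg(crs)
  if (buffer_km <= 0) stop("buffer_km must be positive")
  parts <- if (!is.null(range_polygon$outer)) list(range_polygon) else range_polygon
  if (!length(parts)) stop("invalid polygon: no parts")
  for (p in parts) if (is.null(p$outer)) stop("invalid polygon: part without outer ring")
  parts <- lapply(parts, .project_part, origin = point, crs = crs)
  pt <- if (crs == "planar") as.numeric(point) else c(0, 0)

  inside_part <- function(part) {
    if (!.point_in_ring(pt, part$outer)) return(FALSE)
    for (h in part$holes) if (.point_in_ring(pt, h)) return(FALSE)
    TRUE
  }
  which_in <- which(vapply(parts, inside_part, logical(1)))
  if (!length(which_in)) return(0)

  d <- Inf
  for (part in parts) {
    d <- min(d, .dist_to_ring(pt, part$outer))
    for (h in part$holes) {
      surv <- .eroded_hole_points(h, buffer_km)
      if (nrow(surv)) {
        dh <- min(sqrt((surv[, 1] - pt[1])^2 + (surv[, 2] - pt[2])^2)) - buffer_km
        d <- min(d, dh)
      }
    }
  }
  max(0, d)
}

#' Write species range polygons as GeoJSON
#'
#' One `Feature` per species (geometry `MultiPolygon`), with the species
#' name in `properties$species`.
#'
#' @param ranges Named list (by species) of parts lists (see
#'   [distance_to_edge()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geojson_ranges <- function(ranges, path) {
  features <- lapply(names(ranges), function(sp) {
    polys <- lapply(ranges[[sp]], function(part) {
      rings <- c(list(part$outer), part$holes)
      lapply(rings, function(r) {
        r <- .close_ring(r)
        lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
      })
    })
    list(type = "Feature",
         properties = list(species = sp),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read species range polygons from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features; the species name is taken
#' from `properties$species`.
#'
#' @param path GeoJSON file.
#' @return Named list of parts lists (see [distance_to_edge()]).
#' @export
read_geojson_ranges <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in obj$features) {
    sp <- f$properties$species %||% sprintf("feature%03d", length(out) + 1L)
    geom <- f$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type))
    out[[sp]] <- lapply(polys, function(rings) {
      mats <- lapply(rings, function(r)
        do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]]))))
      list(outer = mats[[1]],
           holes = if (length(mats) > 1) mats[-1] else list())
    })
  }
  out
}
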