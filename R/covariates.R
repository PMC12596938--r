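# Environmental-variability covariates from a gridded productivity raster
# and design-table assembly for the two regression stages.

.cells_in_buffer <- function(raster, center, radius_km, crs) {
  xy <- unique(raster[, c("x", "y")])
  d <- if (crs == "planar") {
    sqrt((xy$x - center[1])^2 + (xy$y - center[2])^2)
  } else {
    p <- .project_local(as.matrix(xy), center)
    sqrt(p[, 1]^2 + p[, 2]^2)
  }
  xy[d <= radius_km, , drop = FALSE]
}

#' Spatial variability of productivity around a location
#'
#' Coefficient of variation across raster cells of the cross-year average
#' productivity: each cell within `radius_km` of the location is averaged
#' over years, then the sample SD of these cell means is divided by their
#' mean.  CV (not SD) is used because productivity is ratio-scale data.
#'
#' @param raster Data frame with columns `x`, `y`, `year`, `value`; cell
#'   coordinates are cell centers.
#' @param center Numeric length-2 location, same coordinate system as the
#'   raster.
#' @param radius_km Buffer radius (default 10 km); a cell belongs to the
#'   buffer iff its center is within the radius.
#' @param crs `"lonlat"` (default) or `"planar"` (km).
#' @return Unitless CV.
#' @export
spatial_cv <- function(raster, center, radius_km = 10,
                       crs = c("lonlat", "planar")) {
  crs <- match.arg(crs)
  cells <- .cells_in_buffer(raster, center, radius_km, crs)
  if (nrow(cells) < 2)
    stop("spatial_cv needs at least 2 raster cells within the buffer")
  means <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- raster$x == cells$x[i] & raster$y == cells$y[i]
    mean(raster$value[sel])
  }, numeric(1))
  m <- mean(means)
  if (m == 0) stop("spatial_cv undefined: mean productivity is zero")
  stats::sd(means) / m
}

#' Temporal variability of productivity around a location
#'
#' For each raster cell within `radius_km`, the across-year CV (sample SD
#' of the cell's yearly values divided by the cell's mean); the location
#' value is the mean of these per-cell CVs.
#'
#' @inheritParams spatial_cv
#' @return Unitless CV.
#' @export
temporal_cv <- function(raster, center, radius_km = 10,
                        crs = c("lonlat", "planar")) {
  crs <- match.arg(crs)
  cells <- .cells_in_buffer(raster, center, radius_km, crs)
  if (nrow(cells) < 1)
    stop("temporal_cv needs at least 1 raster cell within the buffer")
  cvs <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- raster$x == cells$x[i] & raster$y == cells$y[i]
    v <- raster$value[sel]
    if (length(v) < 2)
      stop("temporal_cv needs at least 2 years per cell")
    m <- mean(v)
    if (m == 0) stop("temporal_cv undefined: a cell has zero mean across years")
    stats::sd(v) / m
  }, numeric(1))
  mean(cvs)
}

#' Assemble the within-species regression design table
#'
#' Joins the posterior group CV estimates with the four geographic and
#' environmental covariates: latitude, log distance to the species range
#' edge (small gaps closed), log spatial productivity CV and log temporal
#' productivity CV.  The three logged covariates and latitude are centered
#' within species (no scaling), and the CV estimates and their posterior
#' SDs are multiplied by 1000 to avoid numerically tiny response values.
#'
#' @param group_cvs Data frame from [group_cvs()] (columns `species`,
#'   `location`, `cv_hat`, `tau_hat`, `n_individuals`).
#' @param locations Data frame with columns `species`, `location_id`,
#'   `latitude`, `longitude`.
#' @param raster Productivity raster (see [spatial_cv()]).
#' @param ranges Named list of species range polygons (see
#'   [distance_to_edge()]).
#' @param buffer_km Gap-closing radius for [distance_to_edge()].
#' @param radius_km Raster buffer radius for the variability covariates.
#' @param log_offset_km Offset used in `log(DistEdge + offset)` so that the
#'   zero distances assigned to out-of-range locations stay finite
#'   (default 1 km).
#' @param crs Coordinate system of locations/raster/ranges.
#' @return A data frame of class `within_design` with columns `species`,
#'   `location`, `cv_hat`, `tau_hat` (both x 1000), `lat`, `dist_edge`,
#'   `spat_var`, `temp_var` (centered within species) and the uncentered
#'   versions prefixed `raw_`.
#' @export
assemble_within_design <- function(group_cvs, locations, raster, ranges,
                                   buffer_km = 10, radius_km = 10,
                                   log_offset_km = 1,
                                   crs = c("lonlat", "planar")) {
  crs <- match.arg(crs)
  key <- paste(group_cvs$species, group_cvs$location)
  lkey <- paste(locations$species, locations$location_id)
  idx <- match(key, lkey)
  if (anyNA(idx))
    stop("no location entry for: ",
         paste(key[is.na(idx)], collapse = ", "))
  lat <- locations$latitude[idx]
  lon <- locations$longitude[idx]
  n <- nrow(group_cvs)
  de <- sv <- tv <- numeric(n)
  for (i in seq_len(n)) {
    sp <- group_cvs$species[i]
    if (is.null(ranges[[sp]]))
      stop("no range polygon for species ", sp)
    ctr <- c(lon[i], lat[i])
    de[i] <- distance_to_edge(ctr, ranges[[sp]], buffer_km = buffer_km, crs = crs)
    sv[i] <- spatial_cv(raster, ctr, radius_km = radius_km, crs = crs)
    tv[i] <- temporal_cv(raster, ctr, radius_km = radius_km, crs = crs)
  }
  raw <- cbind(lat = lat, dist_edge = log(de + log_offset_km),
               spat_var = log(sv), temp_var = log(tv))
  if (any(!is.finite(raw)))
    stop("non-finite covariate for: ",
         paste(key[!stats::complete.cases(raw) | rowSums(!is.finite(raw)) > 0],
               collapse = ", "))
  cent <- raw
  for (sp in unique(group_cvs$species)) {
    sel <- group_cvs$species == sp
    cent[sel, ] <- sweep(raw[sel, , drop = FALSE], 2,
                         colMeans(raw[sel, , drop = FALSE]))
  }
  out <- data.frame(species = group_cvs$species,
                    location = group_cvs$location,
                    cv_hat = group_cvs$cv_hat * 1000,
                    tau_hat = group_cvs$tau_hat * 1000,
                    lat = cent[, "lat"], dist_edge = cent[, "dist_edge"],
                    spat_var = cent[, "spat_var"], temp_var = cent[, "temp_var"],
                    raw_lat = raw[, "lat"], raw_dist_edge = raw[, "dist_edge"],
                    raw_spat_var = raw[, "spat_var"], raw_temp_var = raw[, "temp_var"],
                    n_individuals = group_cvs$n_individuals,
                    stringsAsFactors = FALSE)
  class(out) <- c("within_design", "data.frame")
  out
}

#' Assemble the among-species profile table
#'
#' Joins species-level CV estimates with the life-history covariates:
#' generation time, hand-wing index and range size are log-transformed
#' (all right-skewed) and then centered and scaled to unit SD across
#' species; migratory status stays a 0/1 indicator so its effect reads as a
#' migrant-versus-resident contrast.
#'
#' @param species_cvs Data frame from [species_cvs()] (columns `species`,
#'   `cvsp_hat`, `tausp_hat`).
#' @param traits Data frame with columns `species`, `gen_time` (years),
#'   `hwi`, `range_size` (km^2), `mig_status` (0/1).
#' @return A data frame of class `species_profile` with standardised
#'   covariates `gen_time`, `hwi`, `range_size` and binary `mig_status`,
#'   plus `cvsp_hat`/`tausp_hat` on the CV x 1000 scale.
#' @export
species_profiles <- function(species_cvs, traits) {
  idx <- match(species_cvs$species, traits$species)
  if (anyNA(idx))
    stop("no trait entry for species: ",
         paste(species_cvs$species[is.na(idx)], collapse = ", "))
  tr <- traits[idx, ]
  if (!all(tr$mig_status %in% c(0, 1)))
    stop("mig_status must be 0/1")
  out <- data.frame(species = species_cvs$species,
                    cvsp_hat = species_cvs$cvsp_hat * 1000,
                    tausp_hat = species_cvs$tausp_hat * 1000,
                    gen_time = as.numeric(scale(log(tr$gen_time))),
                    hwi = as.numeric(scale(log(tr$hwi))),
                    range_size = as.numeric(scale(log(tr$range_size))),
                    mig_status = tr$mig_status,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_profile", "data.frame")
  out
}

#' Variance inflation factors
#'
#' VIF of each column of a design matrix: `1 / (1 - R^2)` from the
#' ordinary-least-squares regression of that column on all the others.
#' Perfectly collinear columns are reported as `Inf`.
#'
#' @param x Numeric matrix or data frame of covariate columns (more rows
#'   than columns; no constant columns).
#' @return Named numeric vector of VIFs.
#' @export
#' @examples
#' vif(matrix(rnorm(60), ncol = 3))
vif <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x)) stop("vif needs more rows than columns")
  if (any(apply(x, 2, stats::sd) == 0)) stop("vif: constant column")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  vapply(seq_len(ncol(x)), function(p) {
    fit <- stats::lm.fit(cbind(1, x[, -p, drop = FALSE]), x[, p])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, p] - mean(x[, p]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(x))
}
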