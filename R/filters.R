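# Data-cleaning and inclusion rules for raw capture tables.
#
# Records are never modified, only included or excluded; every exclusion is
# recorded with its stage and reason so provenance is queryable.

#' Filtering thresholds
#'
#' @param min_individuals_per_location Minimum captures per
#'   location-by-species group (default 15).
#' @param min_locations_per_species Minimum surviving locations per species
#'   (default 5).
#' @param min_latitude_span Minimum latitude span (degrees, max minus min
#'   over surviving locations) per species (default 5).
#' @param mad_multiplier Outlier threshold in raw median absolute
#'   deviations (default 5).
#' @param season_window Integer months `(start, end)` of the breeding-season
#'   sampling window (default April-August).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_individuals_per_location = 15,
                          min_locations_per_species = 5,
                          min_latitude_span = 5,
                          mad_multiplier = 5,
                          season_window = c(4L, 8L)) {
  stopifnot(min_individuals_per_location > 0, min_locations_per_species > 0,
            min_latitude_span > 0, mad_multiplier > 0,
            length(season_window) == 2)
  structure(list(min_individuals_per_location = min_individuals_per_location,
                 min_locations_per_species = min_locations_per_species,
                 min_latitude_span = min_latitude_span,
                 mad_multiplier = mad_multiplier,
                 season_window = as.integer(season_window)),
            class = "filter_config")
}

#' Keep only adult male captures
#'
#' Females are excluded because body mass varies strongly with reproductive
#' stage; juveniles because age confounds trait means.  The number of
#' removed records is attached as attribute `n_removed`.
#'
#' @param records Capture data frame with columns `age_class`
#'   (`adult`/`juvenile`/`unknown`) and `sex` (`M`/`F`/`U`).
#' @return The subset of adult-male records (possibly empty).
#' @export
subset_adult_males <- function(records) {
  stopifnot(all(c("age_class", "sex") %in% names(records)))
  keep <- records$age_class == "adult" & records$sex == "M"
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep only the first capture of each individual per season
#'
#' For every (band id, species, location, year) combination, retains the
#' earliest-dated record; date ties are broken by stable input order.  The
#' same individual captured in different years contributes one record per
#' year.
#'
#' @param records Capture data frame with columns `band_id`, `species`,
#'   `location_id` and parseable `date`.
#' @return Deduplicated records in original order.
#' @export
first_capture_per_season <- function(records) {
  d <- if (inherits(records$date, "Date")) records$date
  else as.Date(as.character(records$date), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("unparseable date in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  year <- as.integer(format(d, "%Y"))
  key <- paste(records$band_id, records$species, records$location_id, year,
               sep = "\r")
  ord <- order(key, d, seq_along(key))
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  records[keep, , drop = FALSE]
}

#' Median-absolute-deviation outlier rule
#'
#' Flags values farther than `multiplier` raw MADs from the median, where
#' the MAD is the plain median of absolute deviations from the median
#' (no consistency constant).  A zero MAD (at least half the values tied at
#' the median) removes nothing and emits a warning.
#'
#' @param values Finite numeric vector (non-empty).
#' @param multiplier Positive threshold multiplier (default 5).
#' @return List with integer index vectors `kept` and `removed`.
#' @export
#' @examples
#' mad_outlier_filter(c(9, 10, 10, 10, 11, 30))
mad_outlier_filter <- function(values, multiplier = 5) {
  if (length(values) == 0) stop("mad_outlier_filter: empty input")
  if (!all(is.finite(values))) stop("mad_outlier_filter: values must be finite")
  if (multiplier <= 0) stop("mad_outlier_filter: multiplier must be positive")
  med <- stats::median(values)
  dev <- abs(values - med)
  mad_raw <- stats::median(dev)
  if (mad_raw == 0) {
    warning("MAD is zero; no values removed")
    return(list(kept = seq_along(values), removed = integer(0)))
  }
  removed <- which(dev > multiplier * mad_raw)
  list(kept = setdiff(seq_along(values), removed), removed = removed)
}

#' Apply the sample-size and spatial-extent inclusion criteria
#'
#' Drops location-by-species groups with fewer than
#' `min_individuals_per_location` records, then species left with fewer
#' than `min_locations_per_species` locations or spanning less than
#' `min_latitude_span` degrees of latitude, iterating the two rules until a
#' fixed point is reached (dropping groups can break a species' criteria).
#'
#' @param records Capture data frame (already deduplicated and
#'   outlier-filtered) with columns `species`, `location_id`, `latitude`.
#' @param cfg A [filter_config()].
#' @return List with elements `records` (surviving rows) and `report`
#'   (data frame of per-pass drop counts).
#' @export
apply_inclusion_criteria <- function(records, cfg = filter_config()) {
  report <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    grp <- paste(records$species, records$location_id, sep = "\r")
    n_by_grp <- table(grp)
    small <- names(n_by_grp)[n_by_grp < cfg$min_individuals_per_location]
    records_g <- records[!(grp %in% small), , drop = FALSE]

    loc_tab <- unique(records_g[, c("species", "location_id", "latitude")])
    n_loc <- table(loc_tab$species)
    span <- tapply(loc_tab$latitude, loc_tab$species,
                   function(x) diff(range(x)))
    drop_sp <- names(n_loc)[n_loc < cfg$min_locations_per_species |
                              span[names(n_loc)] < cfg$min_latitude_span]
    records_s <- records_g[!(records_g$species %in% drop_sp), , drop = FALSE]

    report[[pass]] <- data.frame(
      pass = pass,
      groups_dropped = length(small),
      species_dropped = length(drop_sp),
      records_in = nrow(records), records_out = nrow(records_s))
    done <- nrow(records_s) == nrow(records)
    records <- records_s
    if (done || nrow(records) == 0) break
  }
  list(records = records, report = do.call(rbind, report))
}

#' Run the full cleaning pipeline on raw captures
#'
#' Applies, in order: the breeding-season window, the adult-male subset,
#' first-capture-per-season deduplication, the per-group MAD outlier rule on
#' the raw trait scale (independently for each trait, so a record missing or
#' outlying in one trait still contributes to the other), and the inclusion
#' criteria iterated to a fixed point.  The full pipeline is idempotent.
#'
#' @param records Raw capture data frame (see [simulate_captures()] for the
#'   column layout).
#' @param cfg A [filter_config()].
#' @param traits Trait columns to clean (default `c("mass", "wing")`).
#' @return An object of class `filtered_captures`: a list with one cleaned
#'   data frame per trait (`$trait$mass`, ...), an `exclusions` data frame
#'   (trait, stage, band id, row) recording the provenance of every removed
#'   record, and the inclusion `report`s.
#' @export
filter_captures <- function(records, cfg = filter_config(),
                            traits = c("mass", "wing")) {
  stopifnot(inherits(cfg, "filter_config"))
  records$.row <- seq_len(nrow(records))
  excl <- list()
  note <- function(trait, stage, rows) {
    if (length(rows))
      excl[[length(excl) + 1L]] <<- data.frame(
        trait = trait, stage = stage,
        band_id = records$band_id[match(rows, records$.row)],
        row = rows, stringsAsFactors = FALSE)
  }

  mth <- as.integer(format(as.Date(records$date), "%m"))
  in_season <- mth >= cfg$season_window[1] & mth <= cfg$season_window[2]
  base <- records[in_season, , drop = FALSE]
  note("all", "season_window", records$.row[!in_season])

  am <- subset_adult_males(base)
  note("all", "adult_male", setdiff(base$.row, am$.row))

  dedup <- first_capture_per_season(am)
  note("all", "first_capture", setdiff(am$.row, dedup$.row))

  out <- list(trait = list(), report = list())
  for (tr in traits) {
    cur <- dedup[!is.na(dedup[[tr]]), , drop = FALSE]
    note(tr, "missing_trait", setdiff(dedup$.row, cur$.row))
    grp <- paste(cur$species, cur$location_id, sep = "\r")
    removed_rows <- integer(0)
    for (g in unique(grp)) {
      sel <- which(grp == g)
      if (length(sel) < 2) next
      res <- withCallingHandlers(
        mad_outlier_filter(cur[[tr]][sel], cfg$mad_multiplier),
        warning = function(w) invokeRestart("muffleWarning"))
      removed_rows <- c(removed_rows, cur$.row[sel[res$removed]])
    }
    note(tr, "mad_outlier", removed_rows)
    cur <- cur[!(cur$.row %in% removed_rows), , drop = FALSE]
    inc <- apply_inclusion_criteria(cur, cfg)
    note(tr, "inclusion_criteria", setdiff(cur$.row, inc$records$.row))
    out$trait[[tr]] <- inc$records
    out$report[[tr]] <- inc$report
  }
  out$exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trait = character(0), stage = character(0),
               band_id = character(0), row = integer(0))
  class(out) <- "filtered_captures"
  out
}

#' @export
print.filtered_captures <- function(x, ...) {
  cat("Filtered captures:\n")
  for (tr in names(x$trait))
    cat(sprintf("  %s: %d records, %d species, %d groups\n", tr,
                nrow(x$trait[[tr]]), length(unique(x$trait[[tr]]$species)),
                nrow(unique(x$trait[[tr]][, c("species", "location_id")]))))
  cat(sprintf("  exclusions recorded: %d\n", nrow(x$exclusions)))
  invisible(x)
}
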