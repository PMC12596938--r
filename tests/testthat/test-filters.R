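.mk_records <- function(n, species = "SPX", location = "L1", lat = 40,
                        mass = 20, year = 2015, band = NULL) {
  data.frame(band_id = band %||% sprintf("Z%04d", seq_len(n)),
             species = species, location_id = location, latitude = lat,
             longitude = 0, date = as.Date(sprintf("%d-06-01", year)),
             age_class = "adult", sex = "M", mass = mass, wing = 60,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("adult-male subset follows the age and sex codes", {
  r <- .mk_records(4)
  r$age_class <- c("adult", "adult", "juvenile", "unknown")
  r$sex <- c("M", "F", "M", "U")
  out <- subset_adult_males(r)
  expect_equal(nrow(out), 1)
  expect_equal(out$band_id, "Z0001")
  expect_equal(attr(out, "n_removed"), 3)

  allam <- .mk_records(5)
  expect_equal(nrow(subset_adult_males(allam)), 5)

  # synthetic contaminants: removed set equals the generator's list
  ds <- small_ds()
  removed <- setdiff(ds$captures$band_id,
                     subset_adult_males(ds$captures)$band_id)
  expect_setequal(removed, ds$truth$contaminants$nontarget_bands)
})

test_that("first capture per season keeps the earliest record per year", {
  r <- .mk_records(2, band = c("B1", "B1"))
  r$date <- as.Date(c("2015-06-09", "2015-05-03"))
  out <- first_capture_per_season(r)
  expect_equal(nrow(out), 1)
  expect_equal(out$date, as.Date("2015-05-03"))

  # different years are separate seasons
  r2 <- .mk_records(2, band = c("B1", "B1"), year = c(2014, 2015))
  expect_equal(nrow(first_capture_per_season(r2)), 2)

  # date ties broken by stable input order
  r3 <- .mk_records(2, band = c("B1", "B1"))
  r3$mass <- c(21, 19)
  expect_equal(first_capture_per_season(r3)$mass, 21)

  r4 <- .mk_records(1)
  r4$date <- "not-a-date"
  expect_error(suppressWarnings(first_capture_per_season(r4)), "row")

  # brute-force group-by on the synthetic dataset
  cap <- subset_adult_males(small_ds()$captures)
  dd <- first_capture_per_season(cap)
  key <- paste(cap$band_id, cap$species, cap$location_id,
               format(as.Date(cap$date), "%Y"))
  expect_equal(nrow(dd), length(unique(key)))
})

test_that("MAD rule matches the hand-computed example and degenerates safely", {
  # median 10, raw MAD 0.5, threshold 2.5 -> only the 30 is removed
  res <- mad_outlier_filter(c(9, 10, 10, 10, 11, 30), 5)
  expect_equal(res$removed, 6L)
  expect_equal(res$kept, 1:5)

  expect_warning(res0 <- mad_outlier_filter(c(10, 10, 10, 10)), "MAD is zero")
  expect_equal(res0$removed, integer(0))

  res1 <- mad_outlier_filter(c(9.8, 10, 10.2, 10.1, 9.9), 5)
  expect_equal(res1$removed, integer(0))

  expect_error(mad_outlier_filter(numeric(0)), "empty")
  expect_error(mad_outlier_filter(c(1, NA)), "finite")
  expect_error(mad_outlier_filter(1:5, multiplier = 0), "positive")
})

test_that("inclusion criteria drop by group size, location count and span", {
  cfg <- filter_config()
  # species at 4 locations of 20 birds each -> dropped (location rule)
  r4 <- do.call(rbind, lapply(1:4, function(j)
    .mk_records(20, location = sprintf("L%d", j), lat = 30 + 2 * j,
                band = sprintf("A%d_%02d", j, 1:20))))
  out4 <- apply_inclusion_criteria(r4, cfg)
  expect_equal(nrow(out4$records), 0)

  # 6 locations but only 3 degrees of latitude -> dropped (span rule)
  r6 <- do.call(rbind, lapply(1:6, function(j)
    .mk_records(20, location = sprintf("L%d", j), lat = 40 + 0.5 * j,
                band = sprintf("A%d_%02d", j, 1:20))))
  expect_equal(nrow(apply_inclusion_criteria(r6, cfg)$records), 0)

  # small groups are dropped first, which can then break the species rules
  r_mix <- rbind(
    do.call(rbind, lapply(1:5, function(j)
      .mk_records(20, location = sprintf("L%d", j), lat = 30 + 2 * j,
                  band = sprintf("A%d_%02d", j, 1:20)))),
    .mk_records(5, location = "L6", lat = 60, band = sprintf("B%02d", 1:5)))
  out_mix <- apply_inclusion_criteria(r_mix, cfg)
  expect_equal(sort(unique(out_mix$records$location_id)), sprintf("L%d", 1:5))
  expect_true(all(out_mix$report$pass >= 1))

  # generator-built dataset satisfies all rules -> zero drops
  clean <- small_filtered()$trait$mass
  out_clean <- apply_inclusion_criteria(clean, cfg)
  expect_equal(nrow(out_clean$records), nrow(clean))
})

test_that("full filter is idempotent and catches all injected outliers", {
  ds <- small_ds()
  f1 <- small_filtered()
  f2 <- filter_captures(f1$trait$mass[, setdiff(names(f1$trait$mass), ".row")])
  expect_equal(f2$trait$mass$band_id, f1$trait$mass$band_id)
  expect_equal(f2$trait$mass$mass, f1$trait$mass$mass)

  # +/- 8 SD injected outliers must all fall to the 5-MAD rule
  removed_mass <- f1$exclusions$band_id[f1$exclusions$stage == "mad_outlier" &
                                          f1$exclusions$trait == "mass"]
  expect_true(all(ds$truth$contaminants$outlier_bands %in% removed_mass))
  expect_false(any(ds$truth$contaminants$outlier_bands %in%
                     f1$trait$mass$band_id))

  # records are excluded, never modified: surviving rows match the input
  surv <- f1$trait$mass
  orig <- ds$captures[surv$.row, ]
  expect_equal(orig$mass, surv$mass)
  expect_equal(orig$band_id, surv$band_id)

  # provenance: every exclusion carries its stage
  expect_true(all(f1$exclusions$stage %in%
                    c("season_window", "adult_male", "first_capture",
                      "missing_trait", "mad_outlier", "inclusion_criteria")))
})
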