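test_that("distance to range edge matches plane geometry and the gap rule", {
  sq <- unit_square_km()
  expect_equal(distance_to_edge(c(50, 50), sq, crs = "planar"), 50)
  expect_equal(distance_to_edge(c(150, 50), sq, crs = "planar"), 0)
  expect_equal(distance_to_edge(c(10, 40), sq, crs = "planar"), 10)

  # 8-km hole is erased by the 10-km closing: distance equals outer-edge
  hole8 <- list(outer = sq$outer,
                holes = list(cbind(c(46, 54, 54, 46), c(46, 46, 54, 54))))
  expect_equal(distance_to_edge(c(50, 40), hole8, crs = "planar"), 40)

  # 30-km hole survives erosion: nearby point sees the closed gap at the
  # exact analytic distance (eroded hole edge at y = 50, minus the buffer)
  hole30 <- list(outer = sq$outer,
                 holes = list(cbind(c(40, 70, 70, 40), c(40, 40, 70, 70))))
  expect_equal(distance_to_edge(c(50, 35), hole30, crs = "planar"), 5,
               tolerance = 0.2)
  # point inside the gap is outside the range
  expect_equal(distance_to_edge(c(55, 55), hole30, crs = "planar"), 0)

  # shrinking the gap below the buffer diameter restores the no-hole value;
  # enlarging it strictly decreases the distance
  expect_lt(distance_to_edge(c(50, 35), hole30, crs = "planar"),
            distance_to_edge(c(50, 35), hole8, crs = "planar"))
  expect_equal(distance_to_edge(c(50, 35), hole8, crs = "planar"),
               distance_to_edge(c(50, 35), sq, crs = "planar"))

  expect_error(distance_to_edge(c(0, 0), list(), crs = "planar"), "invalid")
})

test_that("distance to edge is 1-Lipschitz and works on lon/lat input", {
  sq <- unit_square_km()
  set.seed(5)
  for (i in 1:20) {
    p <- runif(2, 5, 95)
    q <- p + runif(2, -3, 3)
    d1 <- distance_to_edge(p, sq, crs = "planar")
    d2 <- distance_to_edge(q, sq, crs = "planar")
    expect_lte(abs(d1 - d2), sqrt(sum((p - q)^2)) + 1e-9)
  }

  # lon/lat: a point 0.5 degrees of longitude inside a western edge at
  # latitude 45 is ~0.5 * 111.32 * cos(45 deg) km from it
  rect <- list(outer = cbind(c(-100, -70, -70, -100), c(20, 20, 70, 70)),
               holes = list())
  d <- distance_to_edge(c(-99.5, 45), rect, crs = "lonlat")
  expect_equal(d, 0.5 * 111.32 * cos(45 * pi / 180), tolerance = 0.01)
})

test_that("spatial and temporal CV match hand computations and scale out", {
  r <- expand.grid(x = c(0, 1, 2), y = 0, year = 1:2)
  r$value <- rep(c(10, 10, 10), 2)
  expect_equal(spatial_cv(r, c(1, 0), radius_km = 5, crs = "planar"), 0)

  r$value <- rep(c(8, 10, 12), 2)   # cell means 8, 10, 12: sd 2, mean 10
  expect_equal(spatial_cv(r, c(1, 0), radius_km = 5, crs = "planar"), 0.2)

  r5 <- r; r5$value <- r$value * 5
  expect_equal(spatial_cv(r5, c(1, 0), radius_km = 5, crs = "planar"), 0.2)

  # constant years -> 0 temporal CV
  expect_equal(temporal_cv(r, c(1, 0), radius_km = 5, crs = "planar"), 0)

  r1 <- data.frame(x = 0, y = 0, year = 1:2, value = c(9, 11))
  expect_equal(temporal_cv(r1, c(0, 0), radius_km = 5, crs = "planar"),
               sqrt(2) / 10)

  # two cells with CVs 0.1 and 0.3 -> mean 0.2
  r2 <- rbind(data.frame(x = 0, y = 0, year = 1:2,
                         value = 10 + c(-1, 1) / sqrt(2)),
              data.frame(x = 1, y = 0, year = 1:2,
                         value = 10 + 3 * c(-1, 1) / sqrt(2)))
  expect_equal(temporal_cv(r2, c(0.5, 0), radius_km = 5, crs = "planar"), 0.2)
  expect_equal(temporal_cv(r5, c(1, 0), radius_km = 5, crs = "planar"),
               temporal_cv(r, c(1, 0), radius_km = 5, crs = "planar"))

  expect_error(spatial_cv(r1, c(0, 0), radius_km = 5, crs = "planar"),
               "2 raster cells")
  rz <- data.frame(x = 0, y = 0, year = 1:2, value = c(-1, 1))
  expect_error(temporal_cv(rz, c(0, 0), radius_km = 5, crs = "planar"), "zero")
})

test_that("VIF matches closed forms", {
  set.seed(6)
  n <- 40
  a <- as.numeric(scale(rnorm(n)))
  b <- as.numeric(scale(stats::residuals(stats::lm(rnorm(n) ~ a))))
  cvec <- as.numeric(scale(stats::residuals(stats::lm(rnorm(n) ~ a + b))))

  orth <- cbind(a, b, cvec)
  expect_equal(unname(vif(orth)), rep(1, 3), tolerance = 1e-8)

  dup <- cbind(a, a, b)
  expect_true(is.infinite(vif(dup)[1]))

  # two columns with exact sample correlation 0.6 -> VIF 1/(1-0.36)
  x2 <- 0.6 * a + sqrt(1 - 0.36) * b
  expect_equal(unname(vif(cbind(a, x2))), rep(1.5625, 2), tolerance = 1e-8)

  expect_error(vif(cbind(a, rep(1, n))), "constant")
  expect_error(vif(matrix(rnorm(6), 2, 3)), "more rows")
})

test_that("assembled design equals the generator's design up to centering", {
  ds <- small_ds()
  g <- ds$truth$groups
  gcv <- data.frame(species = g$species, location = g$location_id,
                    cv_hat = g$cv_mass, tau_hat = 0.001,
                    n_individuals = g$n_individuals,
                    stringsAsFactors = FALSE)
  des <- assemble_within_design(gcv, ds$locations, ds$raster, ds$ranges)

  expect_equal(des$raw_lat, g$x_lat)
  expect_equal(des$raw_dist_edge, g$x_dist_edge, tolerance = 1e-9)
  expect_equal(des$raw_spat_var, g$x_spat_var, tolerance = 1e-9)
  expect_equal(des$raw_temp_var, g$x_temp_var, tolerance = 1e-9)
  expect_equal(des$cv_hat, g$cv_mass * 1000)

  # centering contract: per-species means of every covariate are ~0
  for (cv in c("lat", "dist_edge", "spat_var", "temp_var"))
    expect_lt(max(abs(tapply(des[[cv]], des$species, mean))), 1e-10)

  # species with an identical covariate everywhere -> centered column of 0s
  loc1 <- data.frame(species = "S", location_id = c("A", "B"),
                     latitude = 45, longitude = c(-100, -90),
                     stringsAsFactors = FALSE)
  mk_cells <- function(lon) rbind(
    data.frame(x = lon, y = 45.01, year = 1:2, value = c(0.4, 0.6)),
    data.frame(x = lon, y = 44.99, year = 1:2, value = c(0.5, 0.7)))
  ras1 <- rbind(mk_cells(-100), mk_cells(-90))
  rng1 <- list(S = list(list(outer = cbind(c(-120, -80, -80, -120),
                                           c(20, 20, 70, 70)),
                             holes = list())))
  gcv1 <- data.frame(species = "S", location = c("A", "B"), cv_hat = 0.02,
                     tau_hat = 0.001, n_individuals = 20,
                     stringsAsFactors = FALSE)
  des1 <- assemble_within_design(gcv1, loc1, ras1, rng1)
  expect_equal(unname(des1$lat), c(0, 0))

  expect_error(assemble_within_design(gcv, ds$locations[0, ], ds$raster,
                                      ds$ranges), "no location")
})
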