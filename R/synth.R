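#' Configuration for the synthetic-data generator
#'
#' Holds every ground-truth parameter of the generative model that the
#' pipeline is later asked to recover.  Defaults emulate the conditions of
#' the North American banding analysis the package implements: the four
#' cross-species within-range effects default to the published body-mass
#' posterior means (latitude, distance to range edge, spatial and temporal
#' environmental variability, on the CV x 1000 scale), the among-species
#' effects default to the published body-mass estimates for generation
#' time, hand-wing index, range size and migratory status, and the grand
#' intercept of 24 corresponds to a mean within-population CV of 0.024.
#'
#' @param n_species Number of species (>= 3).
#' @param n_locations_per_species Banding locations per species.
#' @param n_individuals_range Length-2 integer range; per-group sample sizes
#'   are drawn uniformly from it (min >= 2).
#' @param true_global_effects Cross-species effects of (latitude, log
#'   distance-to-edge, log spatial variability, log temporal variability) on
#'   CV x 1000.
#' @param true_species_effect_sd Positive SDs of species-specific deviations
#'   around each global effect.
#' @param true_zeta Among-species effects of (log generation time, log
#'   hand-wing index, log range size — each standardised — and migratory
#'   status 0/1) on species-level CV x 1000.
#' @param kappa Grand intercept of species-level CV x 1000.
#' @param sigma_theta Process SD of group-level CV x 1000 around its
#'   regression mean.
#' @param sigma_xi Non-phylogenetic process SD of species-level CV x 1000.
#' @param sigma_phylo SD scale of the phylogenetic species intercepts.
#' @param tree_depth Root-to-tip depth of the simulated ultrametric
#'   phylogeny.
#' @param lat_range Latitude band (degrees N) over which locations are
#'   placed uniformly; defaults to the 28-69 degree span of the emulated
#'   monitoring network.
#' @param base_log_mass_range Range of species baseline mean log body mass
#'   (log grams); the default log(10)-log(100) keeps group CVs near the
#'   observed 0.02 magnitude.
#' @param dist_edge_meanlog,dist_edge_sdlog Log-normal parameters (km) of
#'   true distances to the western range edge.
#' @param env_cv_meanlog,env_cv_sdlog Log-normal parameters of the true
#'   spatial/temporal productivity CVs.
#' @param outlier_frac Fraction of gross measurement outliers injected
#'   (placed at +/- 8 group SDs on the log scale so a 5-MAD rule must catch
#'   them).
#' @param duplicate_frac Fraction of individuals given a second same-season
#'   capture.
#' @param nontarget_frac Fraction of extra non-adult-male records injected.
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return An object of class `sim_config`.
#' @seealso [simulate_captures()], [simulate_tree()]
#' @export
sim_config <- function(n_species = 10,
                       n_locations_per_species = 12,
                       n_individuals_range = c(20L, 60L),
                       true_global_effects = c(lat = -0.147, dist_edge = 0.150,
                                               spat_var = 0.280, temp_var = 0.188),
                       true_species_effect_sd = c(0.05, 0.05, 0.10, 0.10),
                       true_zeta = c(gen_time = -2.554, hwi = -0.273,
                                     range_size = 0.261, mig_status = -0.764),
                       kappa = 24,
                       sigma_theta = 1,
                       sigma_xi = 1.5,
                       sigma_phylo = 2,
                       tree_depth = 1,
                       lat_range = c(28, 69),
                       base_log_mass_range = log(c(10, 100)),
                       dist_edge_meanlog = log(50), dist_edge_sdlog = 0.6,
                       env_cv_meanlog = log(0.08), env_cv_sdlog = 0.4,
                       outlier_frac = 0.02,
                       duplicate_frac = 0.05,
                       nontarget_frac = 0.10,
                       seed = 42L) {
  cfg <- list(n_species = as.integer(n_species),
              n_locations_per_species = as.integer(n_locations_per_species),
              n_individuals_range = as.integer(n_individuals_range),
              true_global_effects = unname(true_global_effects),
              true_species_effect_sd = unname(true_species_effect_sd),
              true_zeta = unname(true_zeta),
              kappa = kappa, sigma_theta = sigma_theta, sigma_xi = sigma_xi,
              sigma_phylo = sigma_phylo, tree_depth = tree_depth,
              lat_range = lat_range,
              base_log_mass_range = base_log_mass_range,
              dist_edge_meanlog = dist_edge_meanlog,
              dist_edge_sdlog = dist_edge_sdlog,
              env_cv_meanlog = env_cv_meanlog, env_cv_sdlog = env_cv_sdlog,
              outlier_frac = outlier_frac, duplicate_frac = duplicate_frac,
              nontarget_frac = nontarget_frac, seed = as.integer(seed))
  if (cfg$n_species < 3) stop("n_species must be >= 3")
  if (cfg$n_individuals_range[1] < 2) stop("n_individuals_range min must be >= 2")
  if (length(cfg$true_global_effects) != 4 || length(cfg$true_zeta) != 4 ||
      length(cfg$true_species_effect_sd) != 4)
    stop("effect vectors must have length 4")
  if (any(cfg$true_species_effect_sd < 0))
    stop("true_species_effect_sd must be non-negative")
  if (any(c(cfg$sigma_theta, cfg$sigma_xi, cfg$sigma_phylo, cfg$tree_depth) <= 0))
    stop("sigma_theta, sigma_xi, sigma_phylo and tree_depth must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric phylogeny
#'
#' Pure-birth (Yule) tree whose branch lengths are rescaled so that every
#' tip sits exactly `depth` units from the root.  Used to induce a known
#' Brownian-motion correlation structure among species intercepts.
#'
#' @param n_species Number of tips (>= 3).
#' @param depth Root-to-tip distance of the returned tree.
#' @param seed Integer seed; the tree is deterministic given the seed.
#' @param labels Optional tip labels (length `n_species`).
#' @return An [ape::rphylo()]-style `phylo` object, ultrametric at `depth`.
#' @export
#' @examples
#' tr <- simulate_tree(5, depth = 2, seed = 1)
#' max(ape::node.depth.edgelength(tr))
simulate_tree <- function(n_species, depth = 1, seed = 1L, labels = NULL) {
  if (n_species < 3) stop("n_species must be >= 3")
  if (depth <= 0) stop("depth must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tip_depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / tip_depth
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_species)
    tree$tip.label <- labels
  } else {
    tree$tip.label <- sprintf("SP%02d", seq_len(n_species))
  }
  tree
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.KM_PER_DEG_LAT <- 110.574
.KM_PER_DEG_LON <- 111.320  # at the equator; scaled by cos(latitude)

#' Simulate a complete synthetic banding dataset with known truth
#'
#' Generates every input the pipeline consumes — capture records, a
#' productivity raster, species range polygons, a species trait table and a
#' phylogeny — from the generative model the pipeline is designed to invert:
#' individual log traits are normal within location-by-species groups, group
#' CVs (x 1000) follow the four-covariate regression with species-specific
#' coefficients, and species-level CVs follow the life-history regression
#' with phylogenetically correlated intercepts.
#'
#' The landscape is constructed so that recomputing the covariates from the
#' emitted raster and polygons reproduces the generating values exactly:
#' each location carries a 3 x 3 raster tile within its 10-km buffer whose
#' cell means and year series realise the drawn spatial and temporal CVs,
#' and each species range is a rectangle whose western edge lies exactly at
#' the drawn distance from each location.  Wing length is linked to body
#' mass isometrically (wing proportional to the cube root of mass, scaled to
#' the species baseline), so the true wing CV is one third of the mass CV.
#'
#' Deliberate contaminants exercise the data-cleaning rules: gross outliers
#' at +/- 8 group SDs, repeat same-season captures of existing band ids, and
#' non-adult-male records.  Their ids are recorded in `truth$contaminants`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `itv_dataset`: a list with elements
#'   `captures`, `locations`, `raster`, `ranges`, `traits`, `tree` and
#'   `truth` (the realised values of every generative parameter).
#' @export
#' @examples
#' ds <- simulate_captures(sim_config(n_species = 3,
#'   n_locations_per_species = 5, n_individuals_range = c(16, 20), seed = 7))
#' nrow(ds$truth$groups)
simulate_captures <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  K <- cfg$n_species
  J <- cfg$n_locations_per_species
  species <- sprintf("SP%02d", seq_len(K))
  tree <- simulate_tree(K, depth = cfg$tree_depth, seed = cfg$seed,
                        labels = species)
  set.seed(cfg$seed)

  ## ---- species level ----
  P <- .phylo_corr_matrix(tree, species)
  L <- t(chol(P + diag(1e-10, K)))
  eta <- as.numeric(L %*% stats::rnorm(K)) * cfg$sigma_phylo

  gen_time <- stats::rlnorm(K, log(2.8), 0.2)     # years (observed range ~1.8-4.3)
  hwi <- stats::rlnorm(K, log(25), 0.3)           # hand-wing index
  range_size <- stats::rlnorm(K, log(3e6), 1.0)   # km^2
  mig_status <- stats::rbinom(K, 1, 0.85)         # most emulated species migrate
  z <- cbind(as.numeric(scale(log(gen_time))),
             as.numeric(scale(log(hwi))),
             as.numeric(scale(log(range_size))),
             mig_status)
  xi <- cfg$kappa + eta + as.numeric(z %*% cfg$true_zeta) +
    stats::rnorm(K, 0, cfg$sigma_xi)

  beta <- sapply(1:4, function(l)
    stats::rnorm(K, cfg$true_global_effects[l], cfg$true_species_effect_sd[l]))
  base_log_mass <- stats::runif(K, cfg$base_log_mass_range[1],
                                cfg$base_log_mass_range[2])

  ## ---- locations and covariates ----
  west_edge <- (seq_len(K) - 1) * 8 - 160         # species range western edges (deg lon)
  loc <- expand.grid(loc_idx = seq_len(J), sp_idx = seq_len(K))
  n_loc <- nrow(loc)
  lat <- stats::runif(n_loc, cfg$lat_range[1], cfg$lat_range[2])
  # enforce >= 25 km separation between any two locations so the 10-km
  # raster buffers never capture a neighbour's cells
  repeat {
    xkm <- (west_edge[loc$sp_idx]) * .KM_PER_DEG_LON * cos(lat * pi / 180)
    done <- TRUE
    for (k in seq_len(K)) {
      sel <- which(loc$sp_idx == k)
      d <- abs(outer(lat[sel], lat[sel], "-")) * .KM_PER_DEG_LAT
      diag(d) <- Inf
      bad <- which(apply(d, 1, min) < 25)
      if (length(bad)) {
        done <- FALSE
        lat[sel[bad[1]]] <- stats::runif(1, cfg$lat_range[1], cfg$lat_range[2])
      }
    }
    if (done) break
  }
  dist_edge <- stats::rlnorm(n_loc, cfg$dist_edge_meanlog, cfg$dist_edge_sdlog)
  spat_var <- stats::rlnorm(n_loc, cfg$env_cv_meanlog, cfg$env_cv_sdlog)
  temp_var <- stats::rlnorm(n_loc, cfg$env_cv_meanlog, cfg$env_cv_sdlog)
  lon <- west_edge[loc$sp_idx] +
    dist_edge / (.KM_PER_DEG_LON * cos(lat * pi / 180))

  x_raw <- cbind(lat = lat,
                 dist_edge = log(dist_edge + 1),
                 spat_var = log(spat_var),
                 temp_var = log(temp_var))
  x_cent <- x_raw
  for (k in seq_len(K)) {
    sel <- loc$sp_idx == k
    x_cent[sel, ] <- sweep(x_raw[sel, , drop = FALSE], 2,
                           colMeans(x_raw[sel, , drop = FALSE]))
  }

  ## ---- group level ----
  theta <- xi[loc$sp_idx] + rowSums(x_cent * beta[loc$sp_idx, , drop = FALSE]) +
    stats::rnorm(n_loc, 0, cfg$sigma_theta)
  theta <- pmax(theta, 1)                         # CV x 1000 must stay positive
  cv_mass <- theta / 1000
  mu_mass <- base_log_mass[loc$sp_idx] + stats::rnorm(n_loc, 0, 0.05)
  sigma_mass <- cv_mass * mu_mass
  mu_wing <- (2 * base_log_mass[loc$sp_idx] + mu_mass) / 3
  sigma_wing <- sigma_mass / 3
  n_pool <- seq(cfg$n_individuals_range[1], cfg$n_individuals_range[2])
  n_ind <- n_pool[sample.int(length(n_pool), n_loc, replace = TRUE)]

  location_id <- sprintf("%s_L%02d", species[loc$sp_idx], loc$loc_idx)

  ## ---- individual captures ----
  cap_list <- vector("list", n_loc)
  band_counter <- 0L
  for (g in seq_len(n_loc)) {
    n <- n_ind[g]
    y <- stats::rnorm(n, mu_mass[g], sigma_mass[g])
    yw <- (2 * base_log_mass[loc$sp_idx[g]] + y) / 3
    yr <- sample(2010:2018, n, replace = TRUE)
    doy <- sample(0:100, n, replace = TRUE)       # Apr 15 + 0..100 days
    cap_list[[g]] <- data.frame(
      band_id = sprintf("B%06d", band_counter + seq_len(n)),
      species = species[loc$sp_idx[g]],
      location_id = location_id[g],
      latitude = lat[g], longitude = lon[g],
      date = as.Date(sprintf("%d-04-15", yr)) + doy,
      age_class = "adult", sex = "M",
      mass = exp(y), wing = exp(yw),
      stringsAsFactors = FALSE)
    band_counter <- band_counter + n
  }
  captures <- do.call(rbind, cap_list)
  group_of <- match(captures$location_id, location_id)

  ## ---- contaminants ----
  n_cap <- nrow(captures)
  n_out <- round(cfg$outlier_frac * n_cap)
  outlier_bands <- character(0)
  if (n_out > 0) {
    g <- sample(seq_len(n_loc), n_out, replace = TRUE)
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    y <- mu_mass[g] + sgn * 8 * sigma_mass[g]
    yw <- (2 * base_log_mass[loc$sp_idx[g]] + y) / 3
    outlier_bands <- sprintf("OUT%05d", seq_len(n_out))
    captures <- rbind(captures, data.frame(
      band_id = outlier_bands, species = species[loc$sp_idx[g]],
      location_id = location_id[g], latitude = lat[g], longitude = lon[g],
      date = as.Date(sprintf("%d-05-01", sample(2010:2018, n_out, TRUE))),
      age_class = "adult", sex = "M", mass = exp(y), wing = exp(yw),
      stringsAsFactors = FALSE))
  }
  n_dup <- round(cfg$duplicate_frac * n_cap)
  duplicate_bands <- character(0)
  if (n_dup > 0) {
    pick <- sample(seq_len(n_cap), n_dup)
    dup <- captures[pick, ]
    g <- group_of[pick]
    y <- stats::rnorm(n_dup, mu_mass[g], sigma_mass[g])
    dup$mass <- exp(y)
    dup$wing <- exp((2 * base_log_mass[loc$sp_idx[g]] + y) / 3)
    dup$date <- dup$date + sample(7:35, n_dup, replace = TRUE)
    duplicate_bands <- dup$band_id
    captures <- rbind(captures, dup)
  }
  n_ntg <- round(cfg$nontarget_frac * n_cap)
  nontarget_bands <- character(0)
  if (n_ntg > 0) {
    g <- sample(seq_len(n_loc), n_ntg, replace = TRUE)
    y <- stats::rnorm(n_ntg, mu_mass[g], sigma_mass[g])
    cls <- sample(c("juvenile-M", "adult-F", "unknown-U"), n_ntg, replace = TRUE)
    nontarget_bands <- sprintf("NTG%05d", seq_len(n_ntg))
    captures <- rbind(captures, data.frame(
      band_id = nontarget_bands, species = species[loc$sp_idx[g]],
      location_id = location_id[g], latitude = lat[g], longitude = lon[g],
      date = as.Date(sprintf("%d-06-01", sample(2010:2018, n_ntg, TRUE))),
      age_class = sub("-.*", "", cls),
      sex = sub(".*-", "", cls),
      mass = exp(y),
      wing = exp((2 * base_log_mass[loc$sp_idx[g]] + y) / 3),
      stringsAsFactors = FALSE))
  }
  rownames(captures) <- NULL

  ## ---- landscape: raster tiles realising SpatVar / TempVar exactly ----
  years <- 2010:2015
  u <- as.numeric(scale(seq_along(years)))        # mean 0, sample SD 1
  v <- as.numeric(scale(1:9))
  offs <- expand.grid(dx = c(-5, 0, 5), dy = c(-5, 0, 5))   # km
  tiles <- vector("list", n_loc)
  for (g in seq_len(n_loc)) {
    m_c <- 0.5 * (1 + spat_var[g] * v)            # cross-year cell means
    cell_lon <- lon[g] + offs$dx / (.KM_PER_DEG_LON * cos(lat[g] * pi / 180))
    cell_lat <- lat[g] + offs$dy / .KM_PER_DEG_LAT
    tiles[[g]] <- data.frame(
      x = rep(cell_lon, each = length(years)),
      y = rep(cell_lat, each = length(years)),
      year = rep(years, 9),
      value = as.numeric(sapply(seq_len(9), function(c)
        m_c[c] * (1 + temp_var[g] * u))))
  }
  raster <- do.call(rbind, tiles)

  ## ---- ranges: rectangles with western edge at the realised distance ----
  ranges <- lapply(seq_len(K), function(k) {
    w <- west_edge[k]
    list(list(outer = cbind(c(w, w + 30, w + 30, w, w),
                            c(-85, -85, 85, 85, -85)),
              holes = list()))
  })
  names(ranges) <- species

  traits <- data.frame(species = species, gen_time = gen_time, hwi = hwi,
                       range_size = range_size, mig_status = mig_status,
                       stringsAsFactors = FALSE)
  locations <- data.frame(species = species[loc$sp_idx],
                          location_id = location_id,
                          latitude = lat, longitude = lon,
                          stringsAsFactors = FALSE)

  truth <- list(
    config = unclass(cfg),
    species = data.frame(species = species, base_log_mass = base_log_mass,
                         eta = eta, xi = xi,
                         beta1 = beta[, 1], beta2 = beta[, 2],
                         beta3 = beta[, 3], beta4 = beta[, 4],
                         z_gen_time = z[, 1], z_hwi = z[, 2],
                         z_range_size = z[, 3], mig_status = mig_status,
                         stringsAsFactors = FALSE),
    groups = data.frame(species = species[loc$sp_idx],
                        location_id = location_id,
                        latitude = lat, longitude = lon,
                        dist_edge_km = dist_edge,
                        spat_var = spat_var, temp_var = temp_var,
                        x_lat = x_raw[, 1], x_dist_edge = x_raw[, 2],
                        x_spat_var = x_raw[, 3], x_temp_var = x_raw[, 4],
                        theta = theta,
                        mu_mass = mu_mass, sigma_mass = sigma_mass,
                        cv_mass = sigma_mass / mu_mass,
                        mu_wing = mu_wing, sigma_wing = sigma_wing,
                        cv_wing = sigma_wing / mu_wing,
                        n_individuals = n_ind,
                        stringsAsFactors = FALSE),
    contaminants = list(outlier_bands = outlier_bands,
                        duplicate_bands = duplicate_bands,
                        nontarget_bands = nontarget_bands),
    tree_newick = ape::write.tree(tree))

  structure(list(captures = captures, locations = locations, raster = raster,
                 ranges = ranges, traits = traits, tree = tree, truth = truth),
            class = "itv_dataset")
}

#' @export
print.itv_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic banding dataset: %d captures, %d species, ",
                     "%d location-by-species groups\n"),
              nrow(x$captures), nrow(x$traits), nrow(x$truth$groups)))
  cat(sprintf("  contaminants: %d outliers, %d duplicate bands, %d non-target records\n",
              length(x$truth$contaminants$outlier_bands),
              length(x$truth$contaminants$duplicate_bands),
              length(x$truth$contaminants$nontarget_bands)))
  invisible(x)
}

#' Write a synthetic dataset to the pipeline's standard input formats
#'
#' Emits `captures.csv`, `locations.csv`, `raster.csv`, `traits.csv`,
#' `ranges.geojson`, `tree.nwk` and `truth.json` into `dir`.
#'
#' @param dataset An `itv_dataset` from [simulate_captures()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "itv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$captures, file.path(dir, "captures.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$locations, file.path(dir, "locations.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$raster, file.path(dir, "raster.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  write_geojson_ranges(dataset$ranges, file.path(dir, "ranges.geojson"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset previously written with [write_dataset()]
#'
#' @param dir Directory containing the standard input files.  `truth.json`
#'   is optional (real data has no truth file).
#' @return An `itv_dataset`.
#' @export
read_dataset <- function(dir) {
  req <- c("captures.csv", "locations.csv", "raster.csv", "traits.csv",
           "ranges.geojson", "tree.nwk")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing))
    stop("missing input files in ", dir, ": ", paste(missing, collapse = ", "))
  captures <- utils::read.csv(file.path(dir, "captures.csv"),
                              stringsAsFactors = FALSE)
  captures$date <- as.Date(captures$date)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(
    captures = captures,
    locations = utils::read.csv(file.path(dir, "locations.csv"),
                                stringsAsFactors = FALSE),
    raster = utils::read.csv(file.path(dir, "raster.csv"),
                             stringsAsFactors = FALSE),
    traits = utils::read.csv(file.path(dir, "traits.csv"),
                             stringsAsFactors = FALSE),
    ranges = read_geojson_ranges(file.path(dir, "ranges.geojson")),
    tree = ape::read.tree(file.path(dir, "tree.nwk")),
    truth = truth), class = "itv_dataset")
}
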