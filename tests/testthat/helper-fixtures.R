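# Shared fixtures, built once per test run.  All datasets are generated in
# code; MCMC fixtures use short chains appropriate for the small problems.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 5 species x 8 locations with all three contaminant types
small_ds <- function() fixture("small_ds",
  simulate_captures(sim_config(n_species = 5, n_locations_per_species = 8,
                               n_individuals_range = c(25, 40), seed = 42)))

small_filtered <- function() fixture("small_filtered",
  filter_captures(small_ds()$captures))

small_cv_fit <- function() fixture("small_cv_fit",
  suppressWarnings(fit_cv_model(small_filtered(), "mass",
    mcmc = mcmc_config(chains = 2, iterations = 4000, warmup = 2000,
                       seed = 7))))

# within-model design built directly from generator truth (no stage-1 MCMC):
# observed CVs are the true theta plus known observation noise tau
truth_design <- function(ds, tau = 1.5, seed = 99) {
  g <- ds$truth$groups
  x <- g[, c("x_lat", "x_dist_edge", "x_spat_var", "x_temp_var")]
  names(x) <- c("lat", "dist_edge", "spat_var", "temp_var")
  for (sp in unique(g$species)) {
    sel <- g$species == sp
    x[sel, ] <- sweep(x[sel, , drop = FALSE], 2, colMeans(x[sel, , drop = FALSE]))
  }
  set.seed(seed)
  data.frame(species = g$species, location = g$location_id,
             cv_hat = g$theta + stats::rnorm(nrow(g), 0, tau),
             tau_hat = tau, x, stringsAsFactors = FALSE)
}

# among-model profile table with known effects, built around a given tree
truth_profiles <- function(tree, zeta, sigma_phylo, sigma_xi = 1, kappa = 24,
                           tau_range = c(0.5, 1.2), seed = 1) {
  set.seed(seed)
  K <- length(tree$tip.label)
  P <- phylo_correlation(tree)$P
  eta <- as.numeric(t(chol(P + diag(1e-10, K))) %*% stats::rnorm(K)) * sigma_phylo
  Z <- cbind(as.numeric(scale(stats::rnorm(K))),
             as.numeric(scale(stats::rnorm(K))),
             as.numeric(scale(stats::rnorm(K))),
             stats::rbinom(K, 1, 0.6))
  xi <- kappa + eta + as.numeric(Z %*% zeta) + stats::rnorm(K, 0, sigma_xi)
  tau <- stats::runif(K, tau_range[1], tau_range[2])
  list(profiles = data.frame(species = tree$tip.label,
                             cvsp_hat = stats::rnorm(K, xi, tau),
                             tausp_hat = tau,
                             gen_time = Z[, 1], hwi = Z[, 2],
                             range_size = Z[, 3], mig_status = Z[, 4],
                             stringsAsFactors = FALSE),
       xi = xi, eta = eta)
}

star_tree <- function(n) {
  tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
             edge.length = rep(1, n),
             tip.label = sprintf("SP%02d", seq_len(n)), Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

unit_square_km <- function(side = 100)
  list(outer = cbind(c(0, side, side, 0), c(0, 0, side, side)), holes = list())
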