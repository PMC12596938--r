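# The fixtures build the regression input directly from generator truth
# (observed CV = true latent CV plus known noise), so these tests isolate
# the measurement-error regression from the trait-model stage.

.within_fixture <- function() fixture("within_fit_main", {
  ds <- simulate_captures(sim_config(n_species = 20,
                                     n_locations_per_species = 15,
                                     true_global_effects = c(-0.15, 0.15, 0.28, 0.07),
                                     outlier_frac = 0, duplicate_frac = 0,
                                     nontarget_frac = 0, seed = 21))
  des <- truth_design(ds, tau = 1.5, seed = 22)
  fit <- suppressWarnings(fit_within_model(des,
    mcmc = mcmc_config(chains = 2, iterations = 2500, warmup = 1250,
                       seed = 23)))
  list(ds = ds, des = des, fit = fit)
})

test_that("within-model fit recovers effect structure with ordered intervals", {
  fx <- .within_fixture()
  fit <- fx$fit
  truth <- fx$ds$truth$config$true_global_effects

  eff <- fit$effects
  expect_setequal(eff$parameter,
                  c("mu_alpha", "mu_beta_lat", "mu_beta_dist_edge",
                    "mu_beta_spat_var", "mu_beta_temp_var", "sigma_theta"))
  # every reported effect carries diagnostics and a gate verdict
  expect_true(all(c("rhat", "ess", "converged") %in% names(eff)))
  expect_true(all(is.finite(eff$rhat)))

  # point estimates land near the generating effects (noisy-design fit)
  betas <- eff$mean[match(paste0("mu_beta_", c("lat", "dist_edge",
                                               "spat_var", "temp_var")),
                          eff$parameter)]
  expect_equal(sign(betas[1]), sign(truth[1]))
  expect_lt(max(abs(betas - truth)), 0.5)

  # 89% interval nested inside the 95% interval for every parameter
  for (p in c(1, 2, 5)) {
    d <- avianITV:::.pool(fit$draws$mu_B)[, p]
    q89 <- stats::quantile(d, c(0.055, 0.945))
    q95 <- stats::quantile(d, c(0.025, 0.975))
    expect_gte(q89[1], q95[1])
    expect_lte(q89[2], q95[2])
  }
})

test_that("noisier observations are shrunk harder toward the regression mean", {
  # two species, matched covariates; one row per species is displaced by +6
  # with small vs large observation noise
  set.seed(31)
  des <- data.frame(
    species = rep(c("A", "B"), each = 10),
    location = rep(sprintf("L%02d", 1:10), 2),
    cv_hat = 24, tau_hat = 0.5,
    lat = rep(seq(-2, 2, length.out = 10), 2),
    dist_edge = stats::rnorm(20, 0, 0.4),
    spat_var = stats::rnorm(20, 0, 0.3), temp_var = stats::rnorm(20, 0, 0.3),
    stringsAsFactors = FALSE)
  des$dist_edge <- ave(des$dist_edge, des$species, FUN = function(x) x - mean(x))
  des$spat_var <- ave(des$spat_var, des$species, FUN = function(x) x - mean(x))
  des$temp_var <- ave(des$temp_var, des$species, FUN = function(x) x - mean(x))
  des$cv_hat <- 24 + 0.2 * des$lat + stats::rnorm(20, 0, 0.3)
  prec_row <- which(des$species == "A" & des$location == "L05")
  noisy_row <- which(des$species == "B" & des$location == "L05")
  des$cv_hat[c(prec_row, noisy_row)] <- des$cv_hat[c(prec_row, noisy_row)] + 6
  des$tau_hat[noisy_row] <- 8

  fit <- suppressWarnings(fit_within_model(des,
    mcmc = mcmc_config(chains = 2, iterations = 2000, warmup = 1000,
                       seed = 32)))
  pull <- des$cv_hat - fit$theta_mean   # displacement absorbed by shrinkage
  expect_gt(pull[noisy_row], pull[prec_row])
  expect_gt(pull[noisy_row], 3)         # tau = 8 >> process SD: mostly noise
})

test_that("rescaling the response rescales every location-scale parameter", {
  # equivariance holds for the likelihood; the weakly-informative priors
  # must be scaled along with the data for the posterior to follow
  fx <- .within_fixture()
  des10 <- fx$des
  des10$cv_hat <- des10$cv_hat * 10
  des10$tau_hat <- des10$tau_hat * 10
  fit10 <- suppressWarnings(fit_within_model(des10,
    mcmc = mcmc_config(chains = 2, iterations = 2500, warmup = 1250,
                       seed = 23),
    priors = list(prior_mu_sd = 50, prior_alpha_sd = 250,
                  prior_scale_sd = 50, wish_scale = 500)))
  e1 <- coef(fx$fit)
  e10 <- coef(fit10)
  expect_equal(unname(e10["mu_alpha"] / e1["mu_alpha"]), 10, tolerance = 0.02)
  expect_equal(unname(e10["mu_beta_lat"] / e1["mu_beta_lat"]), 10,
               tolerance = 0.15)
  expect_equal(unname(e10["sigma_theta"] / e1["sigma_theta"]), 10,
               tolerance = 0.3)
})

test_that("posterior predictive replicates bracket the observed data", {
  fx <- .within_fixture()
  ppc <- posterior_predictive_check(fx$fit, n_rep = 300, seed = 41)
  lim <- stats::quantile(ppc$rep_means, c(0.025, 0.975))
  expect_gt(ppc$obs_mean, lim[1])
  expect_lt(ppc$obs_mean, lim[2])
  # replicate spread reproduces the generating observation-level SD
  expect_lt(abs(mean(ppc$rep_sds) - ppc$obs_sd) / ppc$obs_sd, 0.15)
})

test_that("invalid designs are rejected", {
  fx <- .within_fixture()
  des <- fx$des
  expect_error(fit_within_model(des[des$species == "SP01", ]), "2 species")
  bad_tau <- des; bad_tau$tau_hat[1] <- 0
  expect_error(fit_within_model(bad_tau), "tau_hat")
  degen <- des; degen$dist_edge <- degen$lat
  expect_error(fit_within_model(degen), "rank-deficient")
  expect_error(fit_within_model(des[0, ]), "2 species")
  expect_error(posterior_predictive_check(list()), "within_fit")
})
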