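# Stage 1: hierarchical Bayesian model of log traits per
# location-by-species group, and the uncertainty-propagated CVs derived
# from it.

.cv_model_string <- "
model {
  for (j in 1:G) {
    ybar[j] ~ dnorm(mu[j], n[j] * pow(sigma[j], -2))
    ss[j] ~ dgamma(0.5 * (n[j] - 1), 0.5 * pow(sigma[j], -2))
    mu[j] ~ dnorm(mu_mean[sp[j]], pow(sigma_mean[sp[j]], -2))
    sigma[j] ~ dnorm(mu_sd[sp[j]], pow(sigma_sd[sp[j]], -2)) T(0,)
    cv[j] <- sigma[j] / mu[j]
  }
  for (k in 1:K) {
    mu_mean[k] ~ dnorm(g_mu_mean, pow(p_mu_mean, -2))
    sigma_mean[k] ~ dnorm(g_sigma_mean, pow(p_sigma_mean, -2)) T(0,)
    mu_sd[k] ~ dnorm(g_mu_sd, pow(p_mu_sd, -2)) T(0,)
    sigma_sd[k] ~ dnorm(g_sigma_sd, pow(p_sigma_sd, -2)) T(0,)
  }
  g_mu_mean ~ dnorm(0, pow(prior_loc_sd, -2))
  g_sigma_mean ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  g_mu_sd ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  g_sigma_sd ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  p_mu_mean ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  p_sigma_mean ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  p_mu_sd ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  p_sigma_sd ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
}
"

#' Fit the hierarchical trait-variation model
#'
#' Models the log of the observed trait for individual i in
#' location-by-species group (j, k) as Normal(mu_jk, sigma_jk), with group
#' means normal and group SDs half-normal around species-level parameters,
#' which are themselves exchangeable around global hyperparameters
#' (half-normal meaning a normal with free location truncated at zero).
#' The group CV is derived per posterior draw as `sigma_jk / mu_jk`, so the
#' uncertainty of both moments — including the group sample size — is
#' propagated into the CV estimate.
#'
#' The likelihood enters through the exact sufficient-statistic
#' factorisation of the normal model (group mean ~ Normal(mu, sigma^2 / n),
#' residual sum of squares ~ Gamma((n - 1) / 2, 1 / (2 sigma^2))), which is
#' identical to the per-individual likelihood but makes the cost
#' independent of the number of individuals.
#'
#' @param data A `filtered_captures` object from [filter_captures()], or a
#'   data frame with columns `species`, `location_id` and the trait column.
#' @param trait Trait column to model (`"mass"` or `"wing"`, log-transformed
#'   internally).
#' @param mcmc An [mcmc_config()]; the default mirrors the long chains the
#'   trait hierarchy needs (4 x 50,000, 20,000 warm-up, thinning 20).
#' @param priors List overriding `prior_loc_sd` (SD of the normal prior on
#'   the global location hyperparameter, default 10) and `prior_scale_sd`
#'   (SD of the half-normal priors on all scale-type hyperparameters,
#'   default 5), on the log-trait scale.
#' @param gate List with convergence thresholds `rhat` (default 1.05) and
#'   `ess` (default 400); a fit failing the gate is flagged, not discarded.
#' @return An object of class `cv_fit` with the posterior draws, the group
#'   table, and the convergence gate verdict.  Use [group_cvs()],
#'   [species_cvs()], [derive_group_cv()] and the `print`/`summary`/`coef`/
#'   `plot` methods to inspect it.
#' @export
fit_cv_model <- function(data, trait = c("mass", "wing"),
                         mcmc = mcmc_config(iterations = 50000,
                                            warmup = 20000, thin = 20),
                         priors = NULL,
                         gate = list(rhat = 1.05, ess = 400)) {
  trait <- match.arg(trait)
  if (inherits(data, "filtered_captures")) data <- data$trait[[trait]]
  stopifnot(is.data.frame(data),
            all(c("species", "location_id", trait) %in% names(data)))
  y <- log(data[[trait]])
  if (!all(is.finite(y))) stop("trait values must be positive and finite")
  grp_key <- paste(data$species, data$location_id, sep = "\r")
  groups <- unique(data.frame(species = data$species,
                              location = data$location_id,
                              key = grp_key, stringsAsFactors = FALSE))
  g <- match(grp_key, groups$key)
  n <- as.integer(tabulate(g, nbins = nrow(groups)))
  if (any(n < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(groups$key[n < 2], collapse = ", "))
  ybar <- as.numeric(tapply(y, g, mean))
  ss <- as.numeric(tapply(y, g, function(v) sum((v - mean(v))^2)))
  s <- sqrt(ss / (n - 1))
  species <- unique(groups$species)
  sp <- match(groups$species, species)
  K <- length(species)

  pr <- utils::modifyList(list(prior_loc_sd = 10, prior_scale_sd = 5),
                          priors %||% list())
  jdata <- list(G = nrow(groups), K = K, ybar = ybar, ss = ss, n = n, sp = sp,
                prior_loc_sd = pr$prior_loc_sd,
                prior_scale_sd = pr$prior_scale_sd)
  sp_mean <- as.numeric(tapply(ybar, sp, mean))
  sp_mean_sd <- pmax(as.numeric(tapply(ybar, sp, stats::sd)), 0.02, na.rm = TRUE)
  sp_sd <- as.numeric(tapply(s, sp, mean))
  sp_sd_sd <- pmax(as.numeric(tapply(s, sp, stats::sd)), 0.01, na.rm = TRUE)
  sp_mean_sd[is.na(sp_mean_sd)] <- 0.02
  sp_sd_sd[is.na(sp_sd_sd)] <- 0.01
  inits <- list(mu = ybar, sigma = pmax(s, 1e-4),
                mu_mean = sp_mean, sigma_mean = sp_mean_sd,
                mu_sd = pmax(sp_sd, 1e-4), sigma_sd = sp_sd_sd,
                g_mu_mean = mean(ybar), p_mu_mean = max(stats::sd(sp_mean), 0.05),
                g_sigma_mean = max(mean(sp_mean_sd), 0.02),
                p_sigma_mean = 0.1,
                g_mu_sd = max(mean(sp_sd), 0.01), p_mu_sd = 0.1,
                g_sigma_sd = max(mean(sp_sd_sd), 0.01), p_sigma_sd = 0.1)
  draws <- .run_jags(.cv_model_string, jdata,
                     monitors = c("mu", "sigma", "cv", "mu_mean", "sigma_mean",
                                  "mu_sd", "sigma_sd",
                                  "g_mu_mean", "p_mu_mean", "g_sigma_mean",
                                  "p_sigma_mean", "g_mu_sd", "p_mu_sd",
                                  "g_sigma_sd", "p_sigma_sd"),
                     mcmc = mcmc, inits = inits)

  diag_params <- c("mu", "sigma", "g_mu_mean", "g_mu_sd")
  rh <- es <- numeric(0)
  for (p in diag_params) {
    arr <- draws[[p]]
    if (length(dim(arr)) == 2L) {
      rh <- c(rh, rhat(arr)); es <- c(es, ess(arr))
    } else {
      for (i in seq_len(dim(arr)[3])) {
        m <- .elem(arr, i)
        rh <- c(rh, rhat(m)); es <- c(es, ess(m))
      }
    }
  }
  verdict <- list(rhat_max = max(rh), ess_min = min(es),
                  rhat_threshold = gate$rhat, ess_threshold = gate$ess,
                  converged = max(rh) <= gate$rhat && min(es) > gate$ess)
  if (!verdict$converged)
    warning(sprintf("cv model flagged non-converged (max Rhat %.3f, min ESS %.0f)",
                    verdict$rhat_max, verdict$ess_min))

  structure(list(draws = draws, trait = trait,
                 groups = data.frame(species = groups$species,
                                     location = groups$location,
                                     n_individuals = n, ybar = ybar,
                                     sample_sd = s, stringsAsFactors = FALSE),
                 species = species, sp_index = sp,
                 mcmc = mcmc, priors = pr, gate = verdict),
            class = "cv_fit")
}

# CV draws (iter x chain matrix) for group i, with the positivity check on mu.
.cv_draws_group <- function(fit, i) {
  mu <- .elem(fit$draws$mu, i)
  if (any(mu <= 0))
    stop("posterior draws of mu <= 0 for group ", fit$groups$species[i], "/",
         fit$groups$location[i],
         "; log-scale trait means must be positive (check data units)")
  .elem(fit$draws$cv, i)
}

#' Posterior CV of one location-by-species group
#'
#' Per retained draw, the CV is the group log-scale SD divided by the group
#' log-scale mean; the point estimate `cv_hat` and its uncertainty
#' `tau_hat` are the mean and SD over draws.
#'
#' @param posterior A `cv_fit`, or a list with numeric elements `mu` and
#'   `sigma` holding paired posterior draws of the two group parameters.
#' @param group For a `cv_fit`: group index, or a length-2 character vector
#'   `c(species, location)`.
#' @return List of class `group_cv` with `species`, `location`, `trait`,
#'   `cv_hat`, `tau_hat`, `n_individuals` and the CV `draws`.
#' @export
derive_group_cv <- function(posterior, group = 1L) {
  if (inherits(posterior, "cv_fit")) {
    i <- if (is.character(group)) {
      which(posterior$groups$species == group[1] &
              posterior$groups$location == group[2])
    } else as.integer(group)
    if (length(i) != 1L || is.na(i) || i < 1 || i > nrow(posterior$groups))
      stop("unknown group")
    cvd <- .cv_draws_group(posterior, i)
    out <- list(species = posterior$groups$species[i],
                location = posterior$groups$location[i],
                trait = posterior$trait,
                cv_hat = mean(cvd), tau_hat = stats::sd(as.numeric(cvd)),
                n_individuals = posterior$groups$n_individuals[i],
                draws = cvd)
  } else {
    mu <- as.numeric(posterior$mu); sigma <- as.numeric(posterior$sigma)
    stopifnot(length(mu) == length(sigma))
    if (any(mu <= 0)) stop("posterior draws of mu <= 0")
    cvd <- sigma / mu
    out <- list(species = NA_character_, location = NA_character_,
                trait = NA_character_, cv_hat = mean(cvd),
                tau_hat = stats::sd(cvd), n_individuals = NA_integer_,
                draws = cvd)
  }
  class(out) <- "group_cv"
  out
}

#' @export
print.group_cv <- function(x, ...) {
  cat(sprintf("CV %s/%s (%s): cv_hat %.4f, tau_hat %.5f, n = %s\n",
              x$species, x$location, x$trait, x$cv_hat, x$tau_hat,
              x$n_individuals))
  invisible(x)
}

#' Posterior CV table for all groups of a fit
#'
#' @param fit A `cv_fit`.
#' @return Data frame with one row per location-by-species group: `species`,
#'   `location`, `trait`, `cv_hat`, `tau_hat`, `n_individuals`.
#' @export
group_cvs <- function(fit) {
  stopifnot(inherits(fit, "cv_fit"))
  cvs <- .pool_cv(fit)
  data.frame(species = fit$groups$species, location = fit$groups$location,
             trait = fit$trait,
             cv_hat = colMeans(cvs), tau_hat = apply(cvs, 2, stats::sd),
             n_individuals = fit$groups$n_individuals,
             stringsAsFactors = FALSE)
}

# all-group CV draws pooled over chains: total draws x G matrix
.pool_cv <- function(fit) {
  mu <- .pool(fit$draws$mu)
  if (any(mu <= 0))
    stop("posterior draws of mu <= 0; log-scale trait means must be positive")
  .pool(fit$draws$cv)
}

#' Species-level CV estimates
#'
#' Per posterior draw, the species value is the mean of the group CVs over
#' all the species' locations (the posterior of the species-average CV);
#' `cvsp_hat`/`tausp_hat` are the mean and SD of that derived chain.
#'
#' @param fit A `cv_fit`.
#' @return Data frame with columns `species`, `trait`, `cvsp_hat`,
#'   `tausp_hat`, `n_locations`.
#' @export
species_cvs <- function(fit) {
  stopifnot(inherits(fit, "cv_fit"))
  cvs <- .pool_cv(fit)
  rows <- lapply(seq_along(fit$species), function(k) {
    cols <- which(fit$sp_index == k)
    chain <- rowMeans(cvs[, cols, drop = FALSE])
    data.frame(species = fit$species[k], trait = fit$trait,
               cvsp_hat = mean(chain), tausp_hat = stats::sd(chain),
               n_locations = length(cols), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cv_fit <- function(x, ...) {
  cat(sprintf("Hierarchical CV model fit: trait %s, %d groups, %d species\n",
              x$trait, nrow(x$groups), length(x$species)))
  cat(sprintf("  convergence: max Rhat %.3f (<= %.2f), min ESS %.0f (> %.0f) -> %s\n",
              x$gate$rhat_max, x$gate$rhat_threshold, x$gate$ess_min,
              x$gate$ess_threshold,
              if (x$gate$converged) "passed" else "FLAGGED"))
  invisible(x)
}

#' @export
summary.cv_fit <- function(object, ...) {
  print(object)
  gcv <- group_cvs(object)
  cat(sprintf("  group CV: mean %.4f, range [%.4f, %.4f]\n",
              mean(gcv$cv_hat), min(gcv$cv_hat), max(gcv$cv_hat)))
  invisible(gcv)
}

#' @export
coef.cv_fit <- function(object, ...) {
  gcv <- group_cvs(object)
  stats::setNames(gcv$cv_hat, paste(gcv$species, gcv$location, sep = ":"))
}

#' @export
plot.cv_fit <- function(x, ...) {
  gcv <- group_cvs(x)
  k <- match(gcv$species, unique(gcv$species))
  graphics::plot(jitter(k), gcv$cv_hat, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.7),
                 xlab = "species", ylab = "posterior mean CV",
                 main = sprintf("Group CVs (%s)", x$trait), xaxt = "n", ...)
  graphics::axis(1, at = seq_along(unique(gcv$species)),
                 labels = unique(gcv$species), las = 2, cex.axis = 0.7)
  graphics::segments(jitter(k), gcv$cv_hat - gcv$tau_hat,
                     y1 = gcv$cv_hat + gcv$tau_hat,
                     col = grDevices::adjustcolor("steelblue", 0.4))
  invisible(x)
}
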