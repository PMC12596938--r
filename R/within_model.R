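# Stage 2: measurement-error regression of group CVs (x 1000) on the four
# geographic/environmental covariates, with correlated species-specific
# intercepts and slopes.

.within_model_string <- "
model {
  for (i in 1:N) {
    cvhat[i] ~ dnorm(mu_theta[i], 1 / (tau2[i] + pow(sigma_theta, 2)))
    mu_theta[i] <- B[sp[i], 1] + inprod(X[i, 1:4], B[sp[i], 2:5])
  }
  for (k in 1:K) { B[k, 1:5] ~ dmnorm(mu_B[1:5], Omega[1:5, 1:5]) }
  mu_B[1] ~ dnorm(0, pow(prior_alpha_sd, -2))
  for (d in 2:5) { mu_B[d] ~ dnorm(0, pow(prior_mu_sd, -2)) }
  Omega[1:5, 1:5] ~ dwish(R[1:5, 1:5], wish_df)
  Sigma[1:5, 1:5] <- inverse(Omega)
  sigma_theta ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
}
"

.WITHIN_EFFECTS <- c("intercept", "lat", "dist_edge", "spat_var", "temp_var")

#' Fit the within-species drivers model
#'
#' Treats each group's estimated CV (x 1000) as a noisy observation of a
#' latent true CV: `cv_hat_jk ~ Normal(theta_jk, tau_hat_jk)` with the
#' posterior SD `tau_hat_jk` from the trait model entering as a known
#' observation SD.  The latent state follows
#' `theta_jk ~ Normal(alpha_k + beta_1k Lat + beta_2k DistEdge +
#' beta_3k SpatVar + beta_4k TempVar, sigma_theta)`, and the species
#' coefficient vectors `(alpha_k, beta_1k..beta_4k)` are multivariate
#' normal around the cross-species effects `(mu_alpha, mu_beta1..mu_beta4)`
#' with a free 5 x 5 covariance.
#'
#' The latent `theta_jk` are marginalised out of the sampled likelihood
#' (normal-normal collapse) and recovered exactly from their conditional
#' distribution given each retained draw, so the reported posterior is that
#' of the full two-layer model.
#'
#' @param design A `within_design` table from [assemble_within_design()]
#'   (or any data frame with columns `species`, `cv_hat`, `tau_hat`, `lat`,
#'   `dist_edge`, `spat_var`, `temp_var`; response on the CV x 1000 scale).
#' @param mcmc An [mcmc_config()] (default 4 chains x 5,000, 2,500 warm-up).
#' @param priors List overriding `prior_mu_sd` (normal SD on the
#'   cross-species covariate effects, default 5), `prior_alpha_sd` (normal
#'   SD on the cross-species intercept, default 25 — the intercept lives on
#'   the CV x 1000 data scale, so it needs a wider weakly-informative
#'   prior than the effects), `prior_scale_sd` (half-normal SD on the
#'   process SD, default 5), `wish_df` (Wishart prior df on the coefficient
#'   precision, default 7) and `wish_scale` (diagonal of its scale matrix,
#'   default 5).
#' @param gate Convergence thresholds (`rhat` 1.01, `ess` 400).
#' @return An object of class `within_fit`: cross-species `effects` table
#'   (mean, 89% CI, p(>0), Rhat, ESS per parameter), species coefficient
#'   summary, latent-state summaries (`theta_mean`, `theta_sd`), posterior
#'   draws, and the gate verdict.
#' @export
fit_within_model <- function(design, mcmc = mcmc_config(), priors = NULL,
                             gate = list(rhat = 1.01, ess = 400)) {
  stopifnot(is.data.frame(design))
  need <- c("species", "cv_hat", "tau_hat", "lat", "dist_edge",
            "spat_var", "temp_var")
  stopifnot(all(need %in% names(design)))
  if (any(design$tau_hat <= 0)) stop("tau_hat must be positive for all rows")
  species <- unique(design$species)
  if (length(species) < 2) stop("need at least 2 species")
  sp <- match(design$species, species)
  if (any(tabulate(sp) < 2)) stop("every species needs at least 2 rows")
  X <- as.matrix(design[, c("lat", "dist_edge", "spat_var", "temp_var")])
  if (qr(cbind(1, X))$rank < 5) stop("rank-deficient design matrix")

  pr <- utils::modifyList(list(prior_mu_sd = 5, prior_alpha_sd = 25,
                               prior_scale_sd = 5,
                               wish_df = 7, wish_scale = 5), priors %||% list())
  K <- length(species)
  jdata <- list(N = nrow(design), K = K, cvhat = design$cv_hat,
                tau2 = design$tau_hat^2, X = X, sp = sp,
                R = diag(pr$wish_scale, 5), wish_df = pr$wish_df,
                prior_mu_sd = pr$prior_mu_sd,
                prior_alpha_sd = pr$prior_alpha_sd,
                prior_scale_sd = pr$prior_scale_sd)
  ls_fit <- stats::lm.fit(cbind(1, X), design$cv_hat)
  b0 <- ls_fit$coefficients
  b0[is.na(b0)] <- 0
  inits <- list(mu_B = b0, B = matrix(rep(b0, each = K), nrow = K),
                sigma_theta = max(stats::sd(ls_fit$residuals), 0.1),
                Omega = diag(1, 5))
  draws <- .run_jags(.within_model_string, jdata,
                     monitors = c("mu_B", "B", "Sigma", "sigma_theta"),
                     mcmc = mcmc, inits = inits)

  eff <- list(mu_alpha = .elem(draws$mu_B, 1),
              mu_beta_lat = .elem(draws$mu_B, 2),
              mu_beta_dist_edge = .elem(draws$mu_B, 3),
              mu_beta_spat_var = .elem(draws$mu_B, 4),
              mu_beta_temp_var = .elem(draws$mu_B, 5),
              sigma_theta = draws$sigma_theta)
  effects <- .effects_table(eff, rhat_max = gate$rhat, ess_min = gate$ess)
  verdict <- list(rhat_max = max(effects$rhat), ess_min = min(effects$ess),
                  rhat_threshold = gate$rhat, ess_threshold = gate$ess,
                  converged = all(effects$converged))
  if (!verdict$converged)
    warning(sprintf("within model flagged non-converged (max Rhat %.3f, min ESS %.0f)",
                    verdict$rhat_max, verdict$ess_min))

  theta <- .recover_latent(design$cv_hat, design$tau_hat^2,
                           .within_mu_theta(draws, X, sp),
                           .pool(draws$sigma_theta)^2)

  spc <- .pool(draws$B)   # draws x (K*5), column-major over [k, d]
  species_coef <- do.call(rbind, lapply(seq_len(K), function(k) {
    cols <- k + K * (0:4)
    data.frame(species = species[k], parameter = .WITHIN_EFFECTS,
               mean = colMeans(spc[, cols, drop = FALSE]),
               sd = apply(spc[, cols, drop = FALSE], 2, stats::sd),
               stringsAsFactors = FALSE)
  }))
  rownames(species_coef) <- NULL

  structure(list(effects = effects, species_coef = species_coef,
                 theta_mean = theta$mean, theta_sd = theta$sd,
                 draws = draws, design = design, species = species,
                 sp_index = sp, X = X, mcmc = mcmc, priors = pr,
                 gate = verdict),
            class = "within_fit")
}

# mu_theta draws for every design row: total-draws x N matrix
.within_mu_theta <- function(draws, X, sp) {
  B <- .pool(draws$B)                      # S x (K*5)
  K <- dim(draws$B)[3]
  S <- nrow(B)
  N <- nrow(X)
  out <- matrix(NA_real_, S, N)
  for (k in unique(sp)) {
    rows <- which(sp == k)
    Bk <- B[, k + K * (0:4), drop = FALSE] # S x 5
    out[, rows] <- Bk %*% rbind(1, t(X[rows, , drop = FALSE]))
  }
  out
}

# Exact conditional moments of a latent state marginalised out of the
# likelihood: obs ~ N(latent, sqrt(tau2)), latent ~ N(mu_draws, sqrt(s2)).
# Returns posterior mean/SD per observation (law of total variance over
# draws).
.recover_latent <- function(obs, tau2, mu_draws, s2_draws) {
  S <- nrow(mu_draws)
  n <- length(obs)
  cm <- cv2 <- matrix(NA_real_, S, n)
  for (i in seq_len(n)) {
    w <- s2_draws / (s2_draws + tau2[i])
    cm[, i] <- w * obs[i] + (1 - w) * mu_draws[, i]
    cv2[, i] <- tau2[i] * s2_draws / (s2_draws + tau2[i])
  }
  list(mean = colMeans(cm),
       sd = sqrt(colMeans(cv2) + apply(cm, 2, stats::var)),
       cond_mean = cm, cond_var = cv2)
}

#' @export
print.within_fit <- function(x, ...) {
  cat(sprintf("Within-species CV drivers fit: %d rows, %d species\n",
              nrow(x$design), length(x$species)))
  cat(sprintf("  convergence: max Rhat %.3f (<= %.2f), min ESS %.0f (> %.0f) -> %s\n",
              x$gate$rhat_max, x$gate$rhat_threshold, x$gate$ess_min,
              x$gate$ess_threshold,
              if (x$gate$converged) "passed" else "FLAGGED"))
  print(x$effects, digits = 3)
  invisible(x)
}

#' @export
summary.within_fit <- function(object, ...) {
  print(object)
  invisible(object$effects)
}

#' @export
coef.within_fit <- function(object, ...) {
  stats::setNames(object$effects$mean, object$effects$parameter)
}

#' @export
fitted.within_fit <- function(object, ...) object$theta_mean

#' @export
residuals.within_fit <- function(object, ...)
  object$design$cv_hat - object$theta_mean

#' @export
plot.within_fit <- function(x, ...) {
  e <- x$effects[x$effects$parameter %in%
                   paste0("mu_beta_", c("lat", "dist_edge", "spat_var",
                                        "temp_var")), ]
  graphics::plot(seq_len(nrow(e)), e$mean,
                 ylim = range(e$ci_low89, e$ci_high89, 0), pch = 16,
                 xaxt = "n", xlab = "", ylab = "effect on CV x 1000",
                 main = "Cross-species effects (mean, 89% CI)", ...)
  graphics::axis(1, at = seq_len(nrow(e)),
                 labels = sub("mu_beta_", "", e$parameter))
  graphics::segments(seq_len(nrow(e)), e$ci_low89, y1 = e$ci_high89)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate replicated observations from a within-species fit
#'
#' Draws replicated `cv_hat` tables through both model layers: a latent
#' `theta` from the process layer, then observation noise with the known
#' `tau_hat`.  Used by [posterior_predictive_check()].
#'
#' @param object A `within_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Matrix of `nrow(design)` rows by `nsim` columns.
#' @export
simulate.within_fit <- function(object, nsim = 200, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  mu <- .within_mu_theta(object$draws, object$X, object$sp_index)
  s2 <- .pool(object$draws$sigma_theta)^2
  S <- nrow(mu)
  pick <- sample.int(S, nsim, replace = nsim > S)
  n <- nrow(object$design)
  tau <- object$design$tau_hat
  reps <- sapply(pick, function(s) {
    theta <- stats::rnorm(n, mu[s, ], sqrt(s2[s]))
    stats::rnorm(n, theta, tau)
  })
  reps
}

#' Graphical posterior predictive check data
#'
#' Generates replicated observation tables from the fitted model and
#' summarises how the observed data sit within them (replicate means/SDs
#' and density summaries suitable for plotting).
#'
#' @param fit A `within_fit` or `among_fit`.
#' @param n_rep Number of replicated datasets (default 200).
#' @param seed Optional seed for the replicate draws.
#' @return Object of class `ppc_summary` with the observed vector, the
#'   replicate matrix, and replicate mean/SD summaries.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = NULL) {
  obs <- if (inherits(fit, "within_fit")) fit$design$cv_hat
  else if (inherits(fit, "among_fit")) fit$profiles$cvsp_hat
  else stop("posterior_predictive_check needs a within_fit or among_fit")
  if (length(obs) == 0) stop("empty design: nothing to check")
  reps <- stats::simulate(fit, nsim = n_rep, seed = seed)
  structure(list(observed = obs, replicates = reps,
                 obs_mean = mean(obs), obs_sd = stats::sd(obs),
                 rep_means = colMeans(reps),
                 rep_sds = apply(reps, 2, stats::sd)),
            class = "ppc_summary")
}

#' @export
print.ppc_summary <- function(x, ...) {
  q <- stats::quantile(x$rep_means, c(0.025, 0.975))
  cat(sprintf("PPC: observed mean %.3f vs replicate means [%.3f, %.3f] (95%%)\n",
              x$obs_mean, q[1], q[2]))
  cat(sprintf("     observed SD %.3f vs replicate SD mean %.3f\n",
              x$obs_sd, mean(x$rep_sds)))
  invisible(x)
}

#' @export
plot.ppc_summary <- function(x, ...) {
  graphics::hist(x$rep_means, breaks = 30, col = "grey85", border = "white",
                 main = "Posterior predictive check", xlab = "replicate mean")
  graphics::abline(v = x$obs_mean, col = "firebrick", lwd = 2)
  invisible(x)
}
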