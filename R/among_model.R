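# Stage 3: among-species regression of species-average CVs on life-history
# covariates with phylogenetically correlated intercepts.

#' Phylogenetic correlation matrix from a tree
#'
#' Brownian-motion shared-path construction: for an ultrametric tree of
#' depth T the correlation between two species is the root-to-MRCA path
#' length divided by T (equivalently `1 - d_ab / (2T)` with `d_ab` the
#' patristic distance).  Built from the Brownian variance-covariance matrix
#' ([ape::vcv.phylo()]) rescaled to unit diagonal.  Non-ultrametric trees
#' are accepted with a warning (correlations are then normalised by the
#' tip-specific depths).
#'
#' @param tree A `phylo` object.
#' @param species Character vector of species to include, in the desired
#'   matrix order; all must be tips of the tree.
#' @return Object of class `phylo_correlation`: list with `species`, the
#'   correlation matrix `P` (unit diagonal, symmetric, PSD) and the source
#'   `tree`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_correlation(tr, c("A", "B", "C"))$P
phylo_correlation <- function(tree, species = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  absent <- setdiff(species, tree$tip.label)
  if (length(absent))
    stop("species missing from the tree: ", paste(absent, collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > 1e-8 * max(depths))
    warning("tree is not ultrametric; using tip-specific depths for scaling")
  P <- .phylo_corr_matrix(tree, species)
  structure(list(species = species, P = P, tree = tree),
            class = "phylo_correlation")
}

.phylo_corr_matrix <- function(tree, species) {
  V <- ape::vcv.phylo(tree)
  P <- stats::cov2cor(V)[species, species, drop = FALSE]
  (P + t(P)) / 2
}

#' @export
print.phylo_correlation <- function(x, ...) {
  cat(sprintf("Phylogenetic correlation matrix: %d species, mean off-diagonal %.3f\n",
              length(x$species),
              mean(x$P[upper.tri(x$P)])))
  invisible(x)
}

.among_model_string <- "
model {
  for (k in 1:K) {
    cvsp[k] ~ dnorm(mu_xi[k], 1 / (tau2[k] + pow(sigma_xi, 2)))
    mu_xi[k] <- kappa + eta[k] + inprod(Z[k, 1:4], zeta[1:4])
  }
  eta[1:K] ~ dmnorm(zeros[1:K], Pinv[1:K, 1:K] * pow(sigma_phylo, -2))
  kappa ~ dnorm(0, pow(prior_kappa_sd, -2))
  for (d in 1:4) { zeta[d] ~ dnorm(0, pow(prior_zeta_sd, -2)) }
  sigma_phylo ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
  sigma_xi ~ dnorm(0, pow(prior_scale_sd, -2)) T(0,)
}
"

.AMONG_EFFECTS <- c("gen_time", "hwi", "range_size", "mig_status")

#' Fit the among-species drivers model
#'
#' Treats each species-average CV estimate (x 1000) as a noisy observation
#' of a latent species value: `cvsp_hat_k ~ Normal(xi_k, tausp_hat_k)` with
#' the stage-1 posterior SD as known observation noise, and
#' `xi_k ~ Normal(kappa + eta_k + zeta_1 GenTime + zeta_2 HWI +
#' zeta_3 RangeSize + zeta_4 MigStatus, sigma_xi)`.  The phylogenetic
#' intercepts are jointly multivariate normal,
#' `eta ~ MVN(0, P sigma_phylo^2)`, with `P` the Brownian correlation
#' matrix from the tree (`sigma_phylo` scales the SD, so the covariance is
#' `P` times the squared scale).
#'
#' As in [fit_within_model()], the latent `xi_k` are marginalised out of
#' the sampled likelihood and recovered exactly from their conditional
#' given each draw.
#'
#' @param profiles A `species_profile` table from [species_profiles()] (or
#'   a data frame with columns `species`, `cvsp_hat`, `tausp_hat`,
#'   `gen_time`, `hwi`, `range_size`, `mig_status`; response on the CV x
#'   1000 scale, continuous covariates centered and scaled).
#' @param phylo A `phylo_correlation` (or a `phylo` tree, coerced with the
#'   profile species order).
#' @param mcmc An [mcmc_config()].
#' @param priors List overriding `prior_kappa_sd` (50), `prior_zeta_sd` (5),
#'   `prior_scale_sd` (5).
#' @param gate Convergence thresholds (`rhat` 1.01, `ess` 400).
#' @return An object of class `among_fit` with the `effects` table
#'   (zeta_1..zeta_4 plus intercept and scales), latent `xi` summaries,
#'   posterior draws and the gate verdict.
#' @export
fit_among_model <- function(profiles, phylo, mcmc = mcmc_config(),
                            priors = NULL,
                            gate = list(rhat = 1.01, ess = 400)) {
  stopifnot(is.data.frame(profiles))
  need <- c("species", "cvsp_hat", "tausp_hat", .AMONG_EFFECTS)
  stopifnot(all(need %in% names(profiles)))
  K <- nrow(profiles)
  if (K < 5) stop("need at least 5 species")
  if (any(profiles$tausp_hat <= 0)) stop("tausp_hat must be positive")
  if (inherits(phylo, "phylo"))
    phylo <- phylo_correlation(phylo, profiles$species)
  stopifnot(inherits(phylo, "phylo_correlation"))
  idx <- match(profiles$species, phylo$species)
  if (anyNA(idx))
    stop("species missing from the correlation matrix: ",
         paste(profiles$species[is.na(idx)], collapse = ", "))
  P <- phylo$P[idx, idx]
  Pj <- P + diag(1e-8, K)
  ch <- tryCatch(chol(Pj), error = function(e) NULL)
  if (is.null(ch)) stop("phylogenetic correlation matrix is not positive definite")
  Pinv <- chol2inv(ch)

  pr <- utils::modifyList(list(prior_kappa_sd = 50, prior_zeta_sd = 5,
                               prior_scale_sd = 5), priors %||% list())
  Z <- as.matrix(profiles[, .AMONG_EFFECTS])
  jdata <- list(K = K, cvsp = profiles$cvsp_hat, tau2 = profiles$tausp_hat^2,
                Z = Z, zeros = rep(0, K), Pinv = Pinv,
                prior_kappa_sd = pr$prior_kappa_sd,
                prior_zeta_sd = pr$prior_zeta_sd,
                prior_scale_sd = pr$prior_scale_sd)
  ls_fit <- stats::lm.fit(cbind(1, Z), profiles$cvsp_hat)
  b0 <- ls_fit$coefficients; b0[is.na(b0)] <- 0
  res_sd <- max(stats::sd(ls_fit$residuals), 0.2)
  inits <- list(kappa = b0[1], zeta = b0[-1], eta = rep(0, K),
                sigma_phylo = res_sd / 2, sigma_xi = res_sd / 2)
  draws <- .run_jags(.among_model_string, jdata,
                     monitors = c("kappa", "zeta", "eta", "sigma_phylo",
                                  "sigma_xi"),
                     mcmc = mcmc, inits = inits)

  eff <- list(kappa = draws$kappa,
              zeta_gen_time = .elem(draws$zeta, 1),
              zeta_hwi = .elem(draws$zeta, 2),
              zeta_range_size = .elem(draws$zeta, 3),
              zeta_mig_status = .elem(draws$zeta, 4),
              sigma_phylo = draws$sigma_phylo,
              sigma_xi = draws$sigma_xi)
  effects <- .effects_table(eff, rhat_max = gate$rhat, ess_min = gate$ess)
  verdict <- list(rhat_max = max(effects$rhat), ess_min = min(effects$ess),
                  rhat_threshold = gate$rhat, ess_threshold = gate$ess,
                  converged = all(effects$converged))
  if (!verdict$converged)
    warning(sprintf("among model flagged non-converged (max Rhat %.3f, min ESS %.0f)",
                    verdict$rhat_max, verdict$ess_min))

  mu_xi <- .among_mu_xi(draws, Z)
  xi <- .recover_latent(profiles$cvsp_hat, profiles$tausp_hat^2, mu_xi,
                        .pool(draws$sigma_xi)^2)

  structure(list(effects = effects, xi_mean = xi$mean, xi_sd = xi$sd,
                 draws = draws, profiles = profiles, P = P, mcmc = mcmc,
                 priors = pr, gate = verdict),
            class = "among_fit")
}

# mu_xi draws for every species: total-draws x K
.among_mu_xi <- function(draws, Z) {
  kappa <- .pool(draws$kappa)
  eta <- .pool(draws$eta)          # S x K
  zeta <- .pool(draws$zeta)        # S x 4
  sweep(eta + zeta %*% t(Z), 1, kappa, `+`)
}

#' @export
print.among_fit <- function(x, ...) {
  cat(sprintf("Among-species CV drivers fit: %d species\n", nrow(x$profiles)))
  cat(sprintf("  convergence: max Rhat %.3f (<= %.2f), min ESS %.0f (> %.0f) -> %s\n",
              x$gate$rhat_max, x$gate$rhat_threshold, x$gate$ess_min,
              x$gate$ess_threshold,
              if (x$gate$converged) "passed" else "FLAGGED"))
  print(x$effects, digits = 3)
  invisible(x)
}

#' @export
summary.among_fit <- function(object, ...) {
  print(object)
  invisible(object$effects)
}

#' @export
coef.among_fit <- function(object, ...)
  stats::setNames(object$effects$mean, object$effects$parameter)

#' @export
fitted.among_fit <- function(object, ...) object$xi_mean

#' @export
residuals.among_fit <- function(object, ...)
  object$profiles$cvsp_hat - object$xi_mean

#' @export
plot.among_fit <- function(x, ...) {
  e <- x$effects[x$effects$parameter %in% paste0("zeta_", .AMONG_EFFECTS), ]
  graphics::plot(seq_len(nrow(e)), e$mean,
                 ylim = range(e$ci_low89, e$ci_high89, 0), pch = 16,
                 xaxt = "n", xlab = "", ylab = "effect on species CV x 1000",
                 main = "Among-species effects (mean, 89% CI)", ...)
  graphics::axis(1, at = seq_len(nrow(e)), labels = sub("zeta_", "", e$parameter))
  graphics::segments(seq_len(nrow(e)), e$ci_low89, y1 = e$ci_high89)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate replicated species CV observations from an among-species fit
#'
#' @param object An `among_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Matrix of `K` species rows by `nsim` columns.
#' @export
simulate.among_fit <- function(object, nsim = 200, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  Z <- as.matrix(object$profiles[, .AMONG_EFFECTS])
  mu <- .among_mu_xi(object$draws, Z)
  s2 <- .pool(object$draws$sigma_xi)^2
  pick <- sample.int(nrow(mu), nsim, replace = nsim > nrow(mu))
  tau <- object$profiles$tausp_hat
  sapply(pick, function(s) {
    xi <- stats::rnorm(length(tau), mu[s, ], sqrt(s2[s]))
    stats::rnorm(length(tau), xi, tau)
  })
}
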