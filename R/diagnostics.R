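#' MCMC sampler settings
#'
#' Container for the Markov chain Monte Carlo settings shared by all model
#' fitting functions.  `iterations` counts all iterations per chain including
#' warm-up; the number of retained draws per chain is
#' `(iterations - warmup) / thin`.
#'
#' The package defaults mirror the settings used for the regression stages of
#' the analysis (4 chains of 5,000 iterations, half discarded as warm-up).
#' [fit_cv_model()] substitutes longer defaults (50,000 iterations, 20,000
#' warm-up, thinning 20) appropriate for the trait-level hierarchy.
#'
#' @param chains Number of chains (>= 2; convergence diagnostics need at
#'   least two).
#' @param iterations Total iterations per chain, including warm-up.
#' @param warmup Iterations discarded as adaptation/burn-in (< `iterations`).
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed; chain c uses `seed + c` for its RNG stream, so
#'   the full posterior is reproducible.
#' @return An object of class `mcmc_config`.
#' @export
#' @examples
#' mcmc_config(chains = 2, iterations = 1000, warmup = 500)
mcmc_config <- function(chains = 4, iterations = 5000, warmup = 2500,
                        thin = 1, seed = 1L) {
  stopifnot(chains >= 2, iterations > 0, warmup >= 0, thin >= 1)
  if (warmup >= iterations)
    stop("`warmup` must be smaller than `iterations`")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("MCMC config: %d chains x %d iterations (%d warm-up, thin %d), seed %d\n",
              x$chains, x$iterations, x$warmup, x$thin, x$seed))
  invisible(x)
}

# Coerce draws to an iterations x chains matrix.  Vectors are treated as a
# single chain.
.draws_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

# Rank-normalise pooled draws (fractional offset 3/8), preserving shape.
.rank_normalize <- function(m) {
  s <- length(m)
  z <- stats::qnorm((rank(m, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

# Classic split-Rhat on an iterations x chains matrix (chains already split).
.split_rhat_basic <- function(m) {
  n <- nrow(m) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(m[seq_len(n), , drop = FALSE],
                  m[n + seq_len(n), , drop = FALSE])
  w <- mean(apply(halves, 2, stats::var))
  if (!is.finite(w) || w == 0) return(1.0)
  b <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Potential scale reduction factor (rank-normalised split R-hat)
#'
#' Computes the modern convergence diagnostic: chains are split in half,
#' draws are rank-normalised, and the classic between/within variance ratio
#' is evaluated on both the rank-normalised draws (bulk) and their folded
#' version (tail); the larger of the two is returned.  Chains with zero
#' variance return 1 by convention (a degenerate but self-consistent chain).
#'
#' @param draws A numeric matrix of posterior draws, iterations x chains.
#' @return A single numeric R-hat value.
#' @references Vehtari, Gelman, Simpson, Carpenter & Buerkner (2021),
#'   Bayesian Analysis 16(2).
#' @export
#' @examples
#' set.seed(1)
#' rhat(matrix(rnorm(2000), ncol = 2))
rhat <- function(draws) {
  m <- .draws_matrix(draws)
  if (ncol(m) < 2L) stop("rhat requires draws from at least 2 chains")
  if (nrow(m) < 4L) stop("rhat requires at least 4 draws per chain")
  if (all(m == m[1L])) return(1.0)
  bulk <- .split_rhat_basic(.rank_normalize(m))
  folded <- .split_rhat_basic(.rank_normalize(abs(m - stats::median(m))))
  max(bulk, folded, na.rm = TRUE)
}

#' Effective sample size
#'
#' Autocorrelation-based effective number of independent draws, pooling
#' autocovariance estimates across chains and truncating the autocorrelation
#' sum with Geyer's initial monotone positive sequence.  Independent draws
#' give an ESS close to the total number of draws; perfectly constant draws
#' are degenerate and return 0.
#'
#' @param draws A numeric vector (one chain) or matrix (iterations x chains).
#' @return A single numeric ESS value.
#' @export
#' @examples
#' set.seed(1)
#' ess(rnorm(1000))
ess <- function(draws) {
  m <- .draws_matrix(draws)
  n <- nrow(m); k <- ncol(m)
  if (n * k < 100L) stop("ess requires at least 100 draws")
  if (all(m == m[1L])) return(0)
  chain_var <- apply(m, 2, stats::var)
  w <- mean(chain_var)
  if (w == 0) return(0)
  # biased (divide-by-n) autocovariances per chain, averaged
  max_lag <- n - 1L
  acov <- sapply(seq_len(k), function(j) {
    a <- stats::acf(m[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- if (is.matrix(acov)) rowMeans(acov) else acov
  var_plus <- w * (n - 1) / n
  if (k > 1L) var_plus <- var_plus + stats::var(colMeans(m))
  rho <- 1 - (w - acov) / var_plus     # rho[1] is lag 0 (== acov[1]/var_plus-ish)
  rho[1] <- 1
  # Geyer: sums of adjacent pairs, initial positive then monotone decreasing
  n_pairs <- (length(rho) - 1L) %/% 2L
  tau <- 1
  prev <- Inf
  t <- 1L
  while (t <= n_pairs) {
    pair <- rho[2 * t] + rho[2 * t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + 2 * pair
    t <- t + 1L
  }
  min(n * k / tau, n * k)
}

#' Summarise posterior draws of a scalar parameter
#'
#' Returns the posterior mean, the equal-tailed 89% credible interval (5.5%
#' and 94.5% empirical quantiles, type-7 interpolation), the posterior
#' probability that the parameter is positive (strictly greater than zero),
#' and the convergence diagnostics [rhat()] and [ess()].
#'
#' @param draws Numeric vector or iterations x chains matrix of posterior
#'   draws (>= 100 draws in total).  R-hat is reported as `NA` when the
#'   chain structure is absent (plain vector / single chain).
#' @param name Optional parameter name carried into the result.
#' @param prob Width of the credible interval (default 0.89).
#' @return An object of class `posterior_summary`: a list with elements
#'   `name`, `mean`, `ci` (length 2), `p_gt0`, `rhat`, `ess`, `n_draws`.
#' @export
#' @examples
#' set.seed(1)
#' summarize_effect(rnorm(1000, 2), name = "effect")
summarize_effect <- function(draws, name = NULL, prob = 0.89) {
  m <- .draws_matrix(draws)
  v <- as.numeric(m)
  if (length(v) < 100L) stop("summarize_effect requires at least 100 draws")
  a <- (1 - prob) / 2
  ci <- unname(stats::quantile(v, c(a, 1 - a), type = 7))
  structure(list(
    name = name %||% "parameter",
    mean = mean(v),
    ci = ci,
    p_gt0 = mean(v > 0),
    rhat = if (ncol(m) >= 2L) rhat(m) else NA_real_,
    ess = ess(m),
    n_draws = length(v)
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.4g, 89%% CI [%.4g, %.4g], p(>0) %.2f, Rhat %.3f, ESS %.0f\n",
              x$name, x$mean, x$ci[1], x$ci[2], x$p_gt0,
              x$rhat, x$ess))
  invisible(x)
}

# Summarise every column of a draws list into a data frame, gating on the
# stage-specific convergence thresholds.
.effects_table <- function(draws_list, rhat_max = 1.01, ess_min = 400) {
  rows <- lapply(names(draws_list), function(nm) {
    s <- summarize_effect(draws_list[[nm]], name = nm)
    data.frame(parameter = nm, mean = s$mean, ci_low89 = s$ci[1],
               ci_high89 = s$ci[2], p_gt0 = s$p_gt0, rhat = s$rhat,
               ess = s$ess, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$converged <- is.finite(out$rhat) & out$rhat <= rhat_max & out$ess > ess_min
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
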