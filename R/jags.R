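# Internal wrapper around rjags shared by all three model-fitting functions.
#
# Returns draws organised per scalar parameter as iterations x chains
# matrices, and per vector/matrix parameter as [iter, chain, index...]
# arrays, so that rhat()/ess() can always see the chain structure.

.run_jags <- function(model_string, data, monitors, mcmc, inits = NULL) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  chain_inits <- lapply(seq_len(mcmc$chains), function(c) {
    ini <- if (is.function(inits)) inits(c) else as.list(inits)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- mcmc$seed + c
    ini
  })
  n_adapt <- max(100L, min(1000L, mcmc$warmup %/% 2L))
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = chain_inits, n.chains = mcmc$chains,
                             n.adapt = n_adapt, quiet = TRUE)
  burn <- mcmc$warmup - n_adapt
  if (burn > 0) stats::update(model, n.iter = burn, progress.bar = "none")
  samples <- rjags::coda.samples(model, variable.names = monitors,
                                 n.iter = mcmc$iterations - mcmc$warmup,
                                 thin = mcmc$thin, progress.bar = "none")
  .collect_draws(samples)
}

# Reshape a coda::mcmc.list into a named list of arrays keyed by base
# parameter name.  Scalars -> [iter, chain]; indexed parameters ("b[2]",
# "S[1,3]") -> [iter, chain, i(, j)].
.collect_draws <- function(samples) {
  vn <- coda::varnames(samples)
  n_iter <- nrow(samples[[1]])
  n_chain <- length(samples)
  base <- sub("\\[.*$", "", vn)
  out <- list()
  for (p in unique(base)) {
    cols <- which(base == p)
    idx_str <- sub("^.*\\[(.*)\\]$", "\\1", vn[cols])
    if (identical(idx_str, vn[cols])) {           # scalar
      m <- sapply(seq_len(n_chain), function(c) samples[[c]][, cols])
      out[[p]] <- matrix(m, nrow = n_iter, ncol = n_chain)
    } else {
      idx <- do.call(rbind, lapply(strsplit(idx_str, ","), as.integer))
      dims <- apply(idx, 2, max)
      arr <- array(NA_real_, dim = c(n_iter, n_chain, dims))
      for (ci in seq_along(cols)) {
        for (ch in seq_len(n_chain)) {
          pos <- cbind(seq_len(n_iter), ch,
                       matrix(rep(idx[ci, ], each = n_iter), nrow = n_iter))
          arr[pos] <- as.numeric(samples[[ch]][, cols[ci]])
        }
      }
      out[[p]] <- arr
    }
  }
  out
}

# Extract element `i` (or [i,j]) of an indexed parameter as an iter x chain
# matrix.
.elem <- function(arr, ...) {
  idx <- list(...)
  d <- dim(arr)
  if (length(d) == 2L) {         # length-1 parameter monitored without index
    stopifnot(all(unlist(idx) == 1L))
    return(arr)
  }
  args <- c(list(arr, TRUE, TRUE), idx)
  m <- do.call(`[`, args)
  matrix(m, nrow = d[1], ncol = d[2])
}

# Pool an iter x chain (x index) array over chains -> vector or matrix of
# total draws.
.pool <- function(arr) {
  d <- dim(arr)
  if (length(d) == 2L) return(as.numeric(arr))
  matrix(arr, nrow = d[1] * d[2], ncol = prod(d[-(1:2)]))
}
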