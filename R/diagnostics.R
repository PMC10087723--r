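# MCMC convergence diagnostics: split R-hat and effective sample size.
# Classic (non rank-normalised) formulas; adequate for the smooth,
# low-dimensional posteriors this package samples.

#' Split R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain non-stationarity also inflates the statistic.
#'
#' @param chains List of numeric vectors (one per chain) of equal length.
#' @return Scalar R-hat (NA if the draws are essentially constant).
#' @export
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    if (n < 4) return(NA_real_)
    half <- floor(n / 2)
    halves <- c(halves, list(ch[1:half], ch[(n - half + 1):n]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ESS of a single sequence via Geyer's initial positive sequence
.ess_vector <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  lag_max <- min(n - 2, 10 * floor(sqrt(n)))
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[-1]
  # sum pairs (rho_{2t}, rho_{2t+1}) while positive
  s <- 0
  t <- 1
  while (t + 1 <= length(ac)) {
    pair <- ac[t] + ac[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent draws, summed over
#' chains (initial-positive-sequence truncation of the autocorrelation).
#'
#' @inheritParams split_rhat
#' @return Scalar ESS.
#' @export
effective_sample_size <- function(chains) {
  sum(vapply(chains, .ess_vector, 0))
}

# diagnostics table for a list of constrained draw matrices (one per chain)
.mcmc_diagnostics <- function(chains_con) {
  if (length(chains_con) == 0 || ncol(chains_con[[1]]) == 0)
    return(data.frame(param = character(0), rhat = numeric(0), ess = numeric(0)))
  params <- colnames(chains_con[[1]])
  rhat <- ess <- numeric(length(params))
  for (i in seq_along(params)) {
    per_chain <- lapply(chains_con, function(m) m[, i])
    rhat[i] <- split_rhat(per_chain)
    ess[i] <- effective_sample_size(per_chain)
  }
  # constant parameters (e.g. omega pinned by a degenerate eta draw) pass
  rhat[is.na(rhat)] <- 1
  data.frame(param = params, rhat = rhat, ess = ess)
}
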