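#' Gelman-Rubin potential scale reduction factor
#'
#' Convergence diagnostic comparing between- and within-chain variance.
#' With `m` (split) chains of length `n`, chain means `xbar_j` and chain
#' variances `s_j^2`:
#' `B = n * var(xbar_j)`, `W = mean(s_j^2)`,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`.
#' By default each chain is split in half first, so a single drifting chain
#' is also detected. Chains are taken converged when `Rhat < 1.1`.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of at least 4 draws.
#' @param split split each chain in half before computing (default `TRUE`).
#' @return the scalar `Rhat`; `+Inf` (with a warning) when the within-chain
#'   variance is zero.
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  if (nrow(chains) < 4) stop("chains too short (< 4 draws)", call. = FALSE)
  if (split) {
    h <- floor(nrow(chains) / 2)
    chains <- cbind(chains[seq_len(h), , drop = FALSE],
                    chains[h + seq_len(h), , drop = FALSE])
  }
  n <- nrow(chains)
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(means)
  if (W == 0) {
    warning("zero within-chain variance; Rhat undefined")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Geyer's initial monotone positive-sequence estimator on the pooled
#' autocorrelation of each chain, used for Monte-Carlo standard errors
#' (`mcse = sd / sqrt(ess)`).
#'
#' @param chains matrix (iterations x chains), list of vectors, or a single
#'   vector.
#' @return estimated effective number of independent draws.
#' @export
ess <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  v <- mean(apply(chains, 2, var))
  if (v == 0) return(n * m)
  max_lag <- min(n - 1, 1000)
  # chain-averaged autocorrelations
  rho <- rep(0, max_lag + 1)
  for (j in seq_len(m)) {
    x <- chains[, j] - mean(chains[, j])
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    rho <- rho + ac * var(chains[, j]) / v
  }
  rho <- rho / m
  # sum pairs rho_{2t} + rho_{2t+1} while positive, enforce monotone decay
  tau_sum <- 0
  prev <- Inf
  t <- 1
  while (2 * t + 1 <= max_lag + 1) {
    pair <- rho[2 * t] + rho[2 * t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau_sum <- tau_sum + pair
    prev <- pair
    t <- t + 1
  }
  n_eff <- n * m / (1 + 2 * tau_sum)
  max(min(n_eff, n * m), 1)
}
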