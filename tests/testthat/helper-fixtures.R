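# Shared fixtures: small random posteriors and SPD matrices built in code.

random_spd <- function(p, jitter = 0.1) {
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(jitter, p)
}

# A posterior with some accumulated data (n rows of N(0,1) design).
random_posterior <- function(p, n, sigma = 0.5, b = 0.2) {
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- as.vector(X %*% beta) + sigma * rnorm(n)
  fit_posterior(list(X = X, y = y), sigma = sigma, b = b)
}

# Build a posterior whose covariance equals a prescribed SPD matrix: pick
# b below the smallest precision eigenvalue and synthesize data rows.
posterior_with_gamma <- function(Gamma, sigma = 1) {
  A <- solve(Gamma)
  A <- (A + t(A)) / 2
  b <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) / 2
  X <- chol(A - diag(b, nrow(A))) * sigma
  fit_posterior(list(X = X, y = rep(0, nrow(X))), sigma = sigma, b = b)
}

# Brute-force BH step-up: largest k with p_(k) <= k alpha / m, reject those.
bh_oracle <- function(pvals, alpha) {
  m <- length(pvals)
  ord <- order(pvals)
  ps <- pvals[ord]
  ks <- which(ps <= seq_len(m) * alpha / m)
  out <- rep(FALSE, m)
  if (length(ks)) out[ord[seq_len(max(ks))]] <- TRUE
  out
}
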