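# Independent oracles used to check the package's own implementations.
# These deliberately take the slow, literal route.

# Gauss-Hermite nodes/weights for weight exp(-x^2), via the Golub-Welsch
# tridiagonal eigenproblem.
gh_nodes <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Adaptive 25-node Gauss-Hermite marginal log-likelihood for a binomial
# logit model with a single random intercept, evaluated at fixed
# parameters. Each group's integral is centred at its conditional mode and
# scaled by the local curvature.
agq_loglik <- function(m, tot, eta_fixed, grp, sigma, k = 25) {
  gh <- gh_nodes(k)
  total <- 0
  for (g in unique(grp)) {
    idx <- grp == g
    h <- function(u)
      sum(dbinom(m[idx], tot[idx], plogis(eta_fixed[idx] + u), log = TRUE)) +
        dnorm(u, 0, sigma, log = TRUE)
    mode <- optimize(h, c(-10 * sigma - 5, 10 * sigma + 5),
                     maximum = TRUE, tol = 1e-10)$maximum
    d <- 1e-4
    hess <- (h(mode + d) - 2 * h(mode) + h(mode - d)) / d^2
    s <- 1 / sqrt(-hess)
    u_k <- mode + sqrt(2) * s * gh$x
    lg <- vapply(u_k, h, 0) + gh$x^2 + log(gh$w) + log(sqrt(2) * s)
    mx <- max(lg)
    total <- total + mx + log(sum(exp(lg - mx)))
  }
  total
}

# one deep-coverage single-factor toy dataset for the quadrature check
make_glmm_toy <- function(coverage_mean = 2000) {
  n <- 10
  grp <- factor(rep(1:5, each = 2))
  x <- rnorm(n)
  tot <- rpois(n, coverage_mean) + 5
  u <- rnorm(5, 0, 0.5)
  m <- rbinom(n, tot, plogis(-0.3 + 0.4 * x + u[grp]))
  list(m = m, tot = tot, data = data.frame(x = x, grp = grp), grp = grp)
}

# literal step-up Benjamini-Hochberg
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in seq_len(n)) adj[i] <- min(adj[i:n])
  q[o] <- pmin(1, adj)
  q
}

# exhaustive shortest-window search for the highest density interval
hdi_bruteforce <- function(x, mass = 0.95) {
  xs <- sort(x[is.finite(x)])
  n <- length(xs)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - k + 1)) {
    lo <- xs[i]; hi <- xs[i + k - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# closed-form ML variance components for a balanced one-way layout with a
# group-level two-cell fixed effect
balanced_ml_oracle <- function(y, grp, cell) {
  g <- nlevels(grp); k <- length(y) / g
  gm <- tapply(y, grp, mean)
  cellmean <- tapply(y, cell, mean)
  gcell <- cell[!duplicated(grp)]
  SSW <- sum((y - gm[grp])^2)
  SSB <- k * sum((gm - cellmean[gcell])^2)
  sig_e <- SSW / (length(y) - g)
  sig_a <- max(0, (SSB / g - sig_e) / k)
  c(sig_a = sig_a, sig_e = sig_e)
}
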