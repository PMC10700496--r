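# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: densities come from stats::d*, sums are
# written out term by term.

# naive Bernoulli 2PL log-likelihood: plain dbinom over observed cells
oracle_loglik <- function(Y, alpha, beta, theta) {
  ll <- 0
  for (j in seq_len(nrow(Y))) for (i in seq_len(ncol(Y))) {
    if (is.na(Y[j, i])) next
    p <- 1 / (1 + exp(-alpha[i] * (theta[j] - beta[i])))
    ll <- ll + dbinom(Y[j, i], 1, p, log = TRUE)
  }
  ll
}

# Kolmogorov-Smirnov distance between a sample and a CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# classic between/within PSRF written out from the formula
oracle_psrf <- function(chains) {
  n <- length(chains[[1]])
  W <- mean(sapply(chains, var))
  B <- n * var(sapply(chains, mean))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# brute-force shortest window containing ceiling(mass * n) sorted points
oracle_hdi <- function(x, mass) {
  s <- sort(x)
  n <- length(s)
  w <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (k in seq_len(n - w + 1)) {
    if (s[k + w - 1] - s[k] < best[2] - best[1]) best <- c(s[k], s[k + w - 1])
  }
  best
}

# EAP by direct numerical integration (independent of the package grid)
oracle_eap <- function(yvec, alpha, beta) {
  lik <- function(th) {
    p <- sapply(seq_along(alpha),
                function(i) 1 / (1 + exp(-alpha[i] * (th - beta[i]))))
    prod(ifelse(yvec == 1, p, 1 - p))
  }
  num <- integrate(Vectorize(function(t) t * lik(t) * dnorm(t)), -8, 8,
                   rel.tol = 1e-10)$value
  den <- integrate(Vectorize(function(t) lik(t) * dnorm(t)), -8, 8,
                   rel.tol = 1e-10)$value
  num / den
}

# a small complete-data response matrix from fixed parameters
make_responses <- function(N, I, seed, tau = c(0.25, 0.90), rho = 0.3) {
  ds <- generate_dataset(generating_condition(N, I, tau, rho, seed = seed))
  ds
}

# reduced chain protocol used by the fast tests
test_chains <- function(seed, n_iter = 1500L, n_burn = 500L) {
  chain_spec(n_chains = 3L, n_iterations = n_iter, n_burnin = n_burn, seed = seed)
}
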