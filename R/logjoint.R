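# Reference log-density builders for the three Bayesian model variants.
# These are the package's formal model definitions; the compiled sampler in
# src/ implements the same densities and is cross-checked against them in the
# test suite.

#' Bernoulli 2PL log-likelihood of the observed responses
#'
#' Missing cells contribute zero. Computed through numerically safe
#' `log(p)` / `log(1 - p)` forms of the logistic.
#'
#' @param y A [response_matrix()].
#' @param items An [item_parameters()] object.
#' @param theta Person abilities, length `nrow(y)`.
#' @return The log-likelihood (a scalar).
#' @export
loglik_2pl <- function(y, items, theta) {
  stopifnot(inherits(y, "response_matrix"), inherits(items, "item_parameters"))
  Y <- y$y
  if (length(theta) != nrow(Y) || length(items$alpha) != ncol(Y))
    stop("dimension mismatch between responses, items and abilities",
         call. = FALSE)
  x <- outer(theta, items$beta, "-") * rep(items$alpha, each = nrow(Y))
  # log p = -log1p(exp(-x)); log(1 - p) = -x - log1p(exp(-x))
  lp <- -log1p(exp(-abs(x))) + pmin(x, 0)
  l1p <- lp - x
  obs <- !is.na(Y)
  sum(ifelse(Y[obs] == 1L, lp[obs], l1p[obs]))
}

#' Log joint density of the non-centered hierarchical 2PL
#'
#' Sum of the Bernoulli log-likelihood and the log priors: standard normal
#' on abilities and item z-scores, N(0, 1) on `mu_alpha`, N(0, 2) on
#' `mu_beta`, the LKJ prior on the correlation Cholesky factor, a flat
#' contribution for the bounded auxiliaries (half-Cauchy / Exponential
#' configurations), or the inverse-Gamma log prior on the directly sampled
#' scales (inverse-Gamma configuration).
#'
#' @param state A [noncentered_state()].
#' @param y A [response_matrix()].
#' @param config A [hyperprior_config()] (half_cauchy, exponential or
#'   inverse_gamma family).
#' @param scale_reading How the second argument of the N(0, 2) priors is
#'   read: `"sd"` (default) or `"variance"`.
#' @return The log joint density (unnormalized posterior).
#' @export
log_joint_hier2pl <- function(state, y, config, scale_reading = c("sd", "variance")) {
  scale_reading <- match.arg(scale_reading)
  stopifnot(inherits(state, "noncentered_state"),
            inherits(config, "hyperprior_config"))
  if (config$family == "inverse_wishart")
    stop("inverse_wishart configures the centered comparator model, not the ",
         "non-centered hierarchical 2PL", call. = FALSE)
  .check_aux_support(state, config)
  cl <- noncentered_to_classical(state, config)
  sd2 <- if (scale_reading == "sd") 2 else sqrt(2)
  lp <- loglik_2pl(y, cl$items, state$theta) +
    sum(stats::dnorm(state$theta, log = TRUE)) +
    sum(stats::dnorm(state$xi_tilde, log = TRUE)) +
    stats::dnorm(state$mu_alpha, 0, 1, log = TRUE) +
    stats::dnorm(state$mu_beta, 0, sd2, log = TRUE) +
    lkj_chol_log_density(state$L_Omega, config$eta)
  if (config$family == "inverse_gamma") {
    lp <- lp + .ig_log_prior(state$tau_alpha, config) +
      .ig_log_prior(state$tau_beta, config)
  }
  lp
}

.check_aux_support <- function(state, config) {
  if (config$family %in% c("half_cauchy", "exponential")) {
    if (is.null(state$tau_alpha_unif) || is.null(state$tau_beta_unif))
      stop("state lacks the bounded auxiliaries required by the ",
           config$family, " configuration", call. = FALSE)
    hi <- if (config$family == "half_cauchy") pi / 2 else 1
    u <- c(state$tau_alpha_unif, state$tau_beta_unif)
    if (any(u <= 0) || any(u >= hi))
      stop(sprintf("auxiliaries must lie strictly inside (0, %s)", format(hi)),
           call. = FALSE)
  }
  invisible(state)
}

# inverse-Gamma(a, b) log density, optionally placed on tau^2 (with the
# Jacobian of tau -> tau^2)
.ig_log_prior <- function(tau, config) {
  a <- config$params$a; b <- config$params$b
  ig <- function(x) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  if (identical(config$params$on, "tau_sq")) ig(tau^2) + log(2 * tau) else ig(tau)
}

#' Log joint density of the centered inverse-Wishart hierarchical 2PL
#'
#' The comparator model: `theta ~ N(0, 1)`,
#' `xi_i = (log alpha_i, beta_i) ~ MVN(mu, Sigma)`, `mu_alpha ~ N(0, 1)`,
#' `mu_beta ~ N(0, 2)`, `Sigma ~ IW(3, I)`.
#'
#' @param params List with `theta`, `log_alpha`, `beta`, `mu` (length 2) and
#'   `Sigma` (2 x 2 symmetric positive definite).
#' @inheritParams log_joint_hier2pl
#' @export
log_joint_iw2pl <- function(params, y, scale_reading = c("sd", "variance"),
                            df = 3, scale_matrix = diag(2)) {
  scale_reading <- match.arg(scale_reading)
  Sigma <- params$Sigma
  if (!isTRUE(all.equal(Sigma, t(Sigma))) ||
      inherits(try(chol(Sigma), silent = TRUE), "try-error"))
    stop("`Sigma` must be symmetric positive definite", call. = FALSE)
  items <- item_parameters(exp(params$log_alpha), params$beta)
  xi <- cbind(params$log_alpha, params$beta)
  sd2 <- if (scale_reading == "sd") 2 else sqrt(2)
  loglik_2pl(y, items, params$theta) +
    sum(stats::dnorm(params$theta, log = TRUE)) +
    sum(.dmvnorm2_log(xi, params$mu, Sigma)) +
    stats::dnorm(params$mu[1L], 0, 1, log = TRUE) +
    stats::dnorm(params$mu[2L], 0, sd2, log = TRUE) +
    dinvwishart_log(Sigma, df = df, scale_matrix = scale_matrix)
}

# bivariate normal log density, rows of x
.dmvnorm2_log <- function(x, mu, Sigma) {
  d <- sweep(x, 2L, mu)
  Si <- solve(Sigma)
  q <- rowSums((d %*% Si) * d)
  -log(2 * pi) - 0.5 * determinant(Sigma, logarithm = TRUE)$modulus[1L] - 0.5 * q
}

#' Inverse-Wishart log density
#'
#' Closed-form density of `Sigma ~ IW(df, scale_matrix)` for a p x p
#' symmetric positive-definite matrix.
#'
#' @param Sigma Symmetric positive-definite matrix.
#' @param df Degrees of freedom, `> p - 1`.
#' @param scale_matrix Positive-definite scale matrix.
#' @export
dinvwishart_log <- function(Sigma, df, scale_matrix) {
  p <- nrow(Sigma)
  if (df <= p - 1) stop("`df` must exceed p - 1", call. = FALSE)
  ldetS <- determinant(scale_matrix, logarithm = TRUE)$modulus[1L]
  ldetX <- determinant(Sigma, logarithm = TRUE)$modulus[1L]
  lgamma_p <- p * (p - 1) / 4 * log(pi) +
    sum(lgamma(df / 2 + (1 - seq_len(p)) / 2))
  df / 2 * ldetS - df * p / 2 * log(2) - lgamma_p -
    (df + p + 1) / 2 * ldetX - 0.5 * sum(diag(scale_matrix %*% solve(Sigma)))
}

#' Log joint density of the nonhierarchical Bayesian 2PL
#'
#' Independent priors: `theta ~ N(0, 1)`, `alpha ~ logN(0, 1)`,
#' `beta ~ N(0, 2)`.
#'
#' @param params List with `theta`, `alpha` (positive) and `beta`.
#' @inheritParams log_joint_hier2pl
#' @export
log_joint_simple2pl <- function(params, y, scale_reading = c("sd", "variance")) {
  scale_reading <- match.arg(scale_reading)
  if (any(params$alpha <= 0))
    stop("discriminations must be strictly positive", call. = FALSE)
  items <- item_parameters(params$alpha, params$beta)
  sd2 <- if (scale_reading == "sd") 2 else sqrt(2)
  loglik_2pl(y, items, params$theta) +
    sum(stats::dnorm(params$theta, log = TRUE)) +
    sum(stats::dlnorm(params$alpha, 0, 1, log = TRUE)) +
    sum(stats::dnorm(params$beta, 0, sd2, log = TRUE))
}
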