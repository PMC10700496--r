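#' Logistic response function
#'
#' Overflow-safe evaluation of `exp(x) / (1 + exp(x))`, the item response
#' function's inverse-logit link.
#'
#' @param x Numeric vector of logits; must be finite.
#' @return Probabilities in (0, 1), with the limiting values 0 and 1 only
#'   attainable up to floating-point resolution.
#' @examples
#' irt_logit(0)    # 0.5
#' irt_logit(2)    # 0.8807971
#' @export
irt_logit <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric", call. = FALSE)
  stats::plogis(x)
}

#' 2PL response probability
#'
#' Probability of a correct response under the two-parameter logistic model,
#' `logit^-1(alpha * (theta - beta))`.
#'
#' @param theta Person ability (logit scale).
#' @param alpha Item discrimination, strictly positive.
#' @param beta Item difficulty (logit scale).
#' @return Response probability in (0, 1). Arguments are recycled.
#' @export
response_probability <- function(theta, alpha, beta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("`alpha` must be finite and strictly positive", call. = FALSE)
  irt_logit(alpha * (theta - beta))
}

#' Bounded-uniform auxiliary transforms for scale hyperpriors
#'
#' Heavy-tailed scale hyperpriors are sampled through bounded auxiliary
#' variables: a Uniform(0, pi/2) variable pushed through `scale * tan(u)` is
#' half-Cauchy(0, scale) distributed, and a Uniform(0, 1) variable pushed
#' through `scale * (-log u)` is Exponential with mean `scale`.
#'
#' @param u Auxiliary value(s), strictly inside the open support:
#'   (0, pi/2) for the tangent transform, (0, 1) for the log transform.
#' @param scale Positive scale: the half-Cauchy scale, respectively the
#'   Exponential mean (the reciprocal of its rate).
#' @return The implied variance-component scale(s), strictly positive.
#' @examples
#' half_cauchy_from_uniform(pi / 4, 2.5)  # the half-Cauchy(0, 2.5) median
#' exponential_from_uniform(exp(-1), 2.5) # 2.5
#' @export
half_cauchy_from_uniform <- function(u, scale) {
  .check_scale(scale)
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= pi / 2))
    stop("`u` must lie strictly inside (0, pi/2)", call. = FALSE)
  # guard the tangent against u numerically indistinguishable from pi/2
  scale * tan(pmin(u, pi / 2 * (1 - 1e-12)))
}

#' @rdname half_cauchy_from_uniform
#' @export
exponential_from_uniform <- function(u, scale) {
  .check_scale(scale)
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("`u` must lie strictly inside (0, 1)", call. = FALSE)
  scale * (-log(u))
}

.check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number", call. = FALSE)
}

#' Unnormalized LKJ log-density of a correlation Cholesky factor
#'
#' For a K x K lower-triangular Cholesky factor L of a correlation matrix,
#' the LKJ prior with shape `eta` has unnormalized density
#' `prod_{k=2..K} L[k,k]^(K - k + 2*eta - 2)`. With `eta = 2` the prior
#' mildly favors correlation matrices near the identity.
#'
#' @param L_Omega Lower-triangular Cholesky factor with positive diagonal and
#'   unit-norm rows.
#' @param eta Positive LKJ shape parameter.
#' @return The log of the unnormalized density.
#' @export
lkj_chol_log_density <- function(L_Omega, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a single positive number", call. = FALSE)
  .check_corr_chol(L_Omega)
  K <- nrow(L_Omega)
  if (K < 2L) return(0)
  k <- 2:K
  sum((K - k + 2 * eta - 2) * log(diag(L_Omega)[k]))
}

.check_corr_chol <- function(L, tol = 1e-8) {
  if (!is.matrix(L) || nrow(L) != ncol(L) || anyNA(L))
    stop("`L_Omega` must be a square numeric matrix", call. = FALSE)
  if (any(abs(L[upper.tri(L)]) > tol))
    stop("`L_Omega` must be lower-triangular", call. = FALSE)
  if (any(diag(L) <= 0))
    stop("`L_Omega` must have a strictly positive diagonal", call. = FALSE)
  if (any(abs(rowSums(L^2) - 1) > 1e-6))
    stop("rows of `L_Omega` must have unit norm (correlation Cholesky factor)",
         call. = FALSE)
  invisible(L)
}

#' Build a 2 x 2 correlation Cholesky factor from a correlation
#'
#' @param rho Correlation in (-1, 1).
#' @return Lower-triangular matrix `rbind(c(1, 0), c(rho, sqrt(1 - rho^2)))`.
#' @export
corr_chol_2d <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop("`rho` must be a single number in (-1, 1)", call. = FALSE)
  matrix(c(1, rho, 0, sqrt(1 - rho^2)), 2L, 2L)
}

#' Map a non-centered state to the classical item parameterization
#'
#' Resolves the variance components from the bounded auxiliaries (or takes
#' them directly under the inverse-Gamma configuration), forms
#' `xi_i = Lambda %*% L_Omega %*% xi_tilde_i` per item with
#' `Lambda = diag(tau_alpha, tau_beta)`, and applies
#' `alpha_i = exp(mu_alpha + xi[1, i])`, `beta_i = mu_beta + xi[2, i]`.
#'
#' @param state A [noncentered_state()].
#' @param config A [hyperprior_config()] with family half_cauchy, exponential
#'   or inverse_gamma.
#' @return A list with elements `items` (an [item_parameters()] object) and
#'   `hyper` (a [hyper_parameters()] object).
#' @export
noncentered_to_classical <- function(state, config) {
  stopifnot(inherits(state, "noncentered_state"),
            inherits(config, "hyperprior_config"))
  if (!config$family %in% c("half_cauchy", "exponential", "inverse_gamma"))
    stop("non-centered reconstruction requires a half_cauchy, exponential or ",
         "inverse_gamma configuration", call. = FALSE)
  tau <- resolve_tau(state, config)
  xi <- diag(c(tau$tau_alpha, tau$tau_beta)) %*% state$L_Omega %*% state$xi_tilde
  items <- item_parameters(alpha = exp(state$mu_alpha + xi[1L, ]),
                           beta = state$mu_beta + xi[2L, ])
  hyper <- hyper_parameters(mu_alpha = state$mu_alpha, mu_beta = state$mu_beta,
                            tau_alpha = tau$tau_alpha, tau_beta = tau$tau_beta,
                            L_Omega = state$L_Omega)
  list(items = items, hyper = hyper)
}

#' @rdname noncentered_to_classical
#' @param items,hyper Classical-parameterization objects to invert back into
#'   z-scores; `hyper` supplies the grand means, scales and Cholesky factor.
#' @param theta Person abilities carried along unchanged.
#' @details `classical_to_noncentered()` inverts the deterministic map for
#'   given positive scales and a valid Cholesky factor, so the round trip
#'   classical -> non-centered -> classical is exact up to floating point.
#'   The auxiliaries are recovered through the inverse of the family
#'   transform (`atan(tau / scale)` and `exp(-tau / scale)`).
#' @export
classical_to_noncentered <- function(items, hyper, config, theta = numeric(0)) {
  stopifnot(inherits(items, "item_parameters"),
            inherits(hyper, "hyper_parameters"),
            inherits(config, "hyperprior_config"))
  xi <- rbind(log(items$alpha) - hyper$mu_alpha, items$beta - hyper$mu_beta)
  z <- solve(hyper$L_Omega, diag(1 / c(hyper$tau_alpha, hyper$tau_beta)) %*% xi)
  aux <- switch(config$family,
    half_cauchy = list(tau_alpha_unif = atan(hyper$tau_alpha / config$params$scale),
                       tau_beta_unif  = atan(hyper$tau_beta / config$params$scale)),
    exponential = {
      sc <- 1 / config$params$inverse_scale
      list(tau_alpha_unif = exp(-hyper$tau_alpha / sc),
           tau_beta_unif  = exp(-hyper$tau_beta / sc))
    },
    inverse_gamma = list(tau_alpha = hyper$tau_alpha, tau_beta = hyper$tau_beta),
    stop("unsupported family", call. = FALSE))
  do.call(noncentered_state,
          c(list(xi_tilde = z, mu_alpha = hyper$mu_alpha, mu_beta = hyper$mu_beta,
                 L_Omega = hyper$L_Omega, theta = theta), aux))
}

#' Resolve variance components from a non-centered state
#'
#' @inheritParams noncentered_to_classical
#' @return List with `tau_alpha` and `tau_beta`.
#' @export
resolve_tau <- function(state, config) {
  switch(config$family,
    half_cauchy = list(
      tau_alpha = half_cauchy_from_uniform(state$tau_alpha_unif, config$params$scale),
      tau_beta  = half_cauchy_from_uniform(state$tau_beta_unif, config$params$scale)),
    exponential = {
      sc <- 1 / config$params$inverse_scale
      list(tau_alpha = exponential_from_uniform(state$tau_alpha_unif, sc),
           tau_beta  = exponential_from_uniform(state$tau_beta_unif, sc))
    },
    inverse_gamma = {
      if (is.null(state$tau_alpha) || is.null(state$tau_beta))
        stop("inverse_gamma configurations sample tau directly; the state must ",
             "carry `tau_alpha` and `tau_beta`", call. = FALSE)
      list(tau_alpha = state$tau_alpha, tau_beta = state$tau_beta)
    },
    stop("unsupported family for tau resolution", call. = FALSE))
}
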