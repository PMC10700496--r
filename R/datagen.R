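# Generating process for the simulation study: truncated bivariate-normal
# item parameters rescaled to an exact target covariance, standard-normal
# abilities, Bernoulli responses.

#' Truncation box for the item-parameter draw
#'
#' The generating draw of the (discrimination, difficulty) pairs is a
#' bivariate normal restricted to a box: grand mean (1, 0), lower limits
#' (0.65, -4.5), upper limits (4.0, 4.5). Defaults reproduce the study's
#' generating condition; infinite limits are allowed for unrestricted draws.
#'
#' @param grand_mean,lower,upper Numeric length-2 vectors.
#' @export
truncation_box <- function(grand_mean = c(1, 0), lower = c(0.65, -4.5),
                           upper = c(4.0, 4.5)) {
  stopifnot(length(grand_mean) == 2L, length(lower) == 2L, length(upper) == 2L)
  if (any(lower >= upper)) stop("`lower` must be below `upper`", call. = FALSE)
  if (any(grand_mean <= lower) || any(grand_mean >= upper))
    stop("`grand_mean` must lie inside the box", call. = FALSE)
  structure(list(grand_mean = as.numeric(grand_mean), lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "truncation_box")
}

#' Design condition of the generating process
#'
#' @param n_persons,n_items Counts (items must be at least 3 so the sample
#'   covariance of the item parameters is nonsingular).
#' @param tau_pair Length-2 positive scales (SD of discriminations, SD of
#'   difficulties). Study levels: small (0.10, 0.40), typical (0.25, 0.90),
#'   extreme (0.75, 1.50); free-form values are allowed.
#' @param rho Target item-parameter correlation in (-1, 1); study levels 0
#'   and 0.3.
#' @param seed Integer seed making the replication reproducible.
#' @export
generating_condition <- function(n_persons, n_items, tau_pair, rho, seed = 1L) {
  stopifnot(n_persons >= 1L, n_items >= 3L, length(tau_pair) == 2L)
  if (any(tau_pair <= 0)) stop("`tau_pair` must be strictly positive", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1)", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons), n_items = as.integer(n_items),
                 tau_pair = as.numeric(tau_pair), rho = rho,
                 seed = as.integer(seed)),
            class = "generating_condition")
}

#' Target item-parameter covariance of a condition
#'
#' `Sigma = tau %*% Omega %*% t(tau)` with `tau = diag(tau_pair)` and
#' `Omega` the correlation matrix with off-diagonal `rho`.
#'
#' @param cond A [generating_condition()].
#' @export
condition_sigma <- function(cond) {
  tau <- diag(cond$tau_pair)
  Omega <- matrix(c(1, cond$rho, cond$rho, 1), 2L, 2L)
  tau %*% Omega %*% t(tau)
}

#' Rejection sampling from a box-truncated bivariate normal
#'
#' Draws from the bivariate normal with the box's grand mean and covariance
#' `cov`, conditioned on falling strictly inside the box.
#'
#' @param n Number of rows to draw.
#' @param box A [truncation_box()].
#' @param cov 2 x 2 positive-definite covariance.
#' @param max_batches Safety cap; if the empirical acceptance rate falls
#'   below 1e-4 the box/covariance combination is deemed infeasible.
#' @return An n x 2 matrix with all rows inside the box.
#' @export
draw_truncated_bvn <- function(n, box, cov, max_batches = 1000L) {
  stopifnot(inherits(box, "truncation_box"), n >= 1L)
  U <- chol(cov)  # errors if not PD
  out <- matrix(NA_real_, 0L, 2L)
  tried <- 0L
  batch <- max(2L * n, 100L)
  for (i in seq_len(max_batches)) {
    z <- matrix(stats::rnorm(2L * batch), batch, 2L) %*% U
    z <- sweep(z, 2L, box$grand_mean, "+")
    keep <- z[, 1L] > box$lower[1L] & z[, 1L] < box$upper[1L] &
            z[, 2L] > box$lower[2L] & z[, 2L] < box$upper[2L]
    out <- rbind(out, z[keep, , drop = FALSE])
    tried <- tried + batch
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
    if (tried >= 1e4 && nrow(out) / tried < 1e-4)
      stop("acceptance rate below 1e-4: infeasible box/covariance combination",
           call. = FALSE)
  }
  stop("truncated draw did not complete within the batch cap", call. = FALSE)
}

#' Rescale a sample to an exact target covariance
#'
#' Centers `Z`, whitens it with the inverse Cholesky factor of its own
#' sample covariance, and colors it with the Cholesky factor of
#' `target_sigma`, so the output's sample covariance equals the target
#' exactly (to floating point), not just in expectation.
#'
#' @param Z n x 2 matrix, n >= 3, with nonsingular sample covariance.
#' @param target_sigma 2 x 2 positive-definite target.
#' @param denominator `"n-1"` (default) or `"n"`: which sample-covariance
#'   convention the exactness is defined against.
#' @return n x 2 matrix with sample covariance `target_sigma` and column
#'   means zero.
#' @export
exact_covariance_rescale <- function(Z, target_sigma, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  stopifnot(is.matrix(Z), ncol(Z) == 2L, nrow(Z) >= 3L)
  Zc <- sweep(Z, 2L, colMeans(Z))
  S <- crossprod(Zc) / (nrow(Z) - (denominator == "n-1"))
  US <- tryCatch(chol(S), error = function(e)
    stop("sample covariance of `Z` is singular", call. = FALSE))
  Zc %*% solve(US) %*% chol(target_sigma)
}

#' True marginal means of a box-truncated bivariate normal
#'
#' Computed by reducing the 2-D moment integrals to 1-D integrals of the
#' closed-form conditional-normal expressions, evaluated with adaptive
#' quadrature (absolute tolerance 1e-10).
#'
#' @param box A [truncation_box()].
#' @param cov 2 x 2 positive-definite covariance of the untruncated normal.
#' @return Length-2 vector of marginal means under truncation.
#' @export
truncated_bvn_means <- function(box, cov) {
  mu <- box$grand_mean
  s1 <- sqrt(cov[1L, 1L]); s2 <- sqrt(cov[2L, 2L])
  r <- cov[1L, 2L] / (s1 * s2)
  lim <- function(l, m, s) c(max(l[1L], m - 10 * s), min(l[2L], m + 10 * s))
  l1 <- lim(c(box$lower[1L], box$upper[1L]), mu[1L], s1)
  l2 <- lim(c(box$lower[2L], box$upper[2L]), mu[2L], s2)
  # P(box) and E[x1 * 1_box] via f(x1) = phi(x1) * P(x2 in box | x1)
  cond_prob <- function(x, m_a, s_a, m_b, s_b, lb) {
    mc <- m_b + r * s_b / s_a * (x - m_a)
    sc <- s_b * sqrt(1 - r^2)
    stats::pnorm(lb[2L], mc, sc) - stats::pnorm(lb[1L], mc, sc)
  }
  int <- function(f, l) stats::integrate(f, l[1L], l[2L], abs.tol = 1e-10,
                                         rel.tol = 1e-10)$value
  p <- int(function(x) stats::dnorm(x, mu[1L], s1) * cond_prob(x, mu[1L], s1, mu[2L], s2, l2), l1)
  if (p <= 0) stop("numeric-moment integration failed: zero mass in box", call. = FALSE)
  m1 <- int(function(x) x * stats::dnorm(x, mu[1L], s1) * cond_prob(x, mu[1L], s1, mu[2L], s2, l2), l1) / p
  m2 <- int(function(x) x * stats::dnorm(x, mu[2L], s2) * cond_prob(x, mu[2L], s2, mu[1L], s1, l1), l2) / p
  c(m1, m2)
}

#' Shift columns to the truncated-normal marginal means
#'
#' Mean-centers each column of `X` and adds the true marginal means of the
#' box-truncated bivariate normal, so the generated grand means are correct
#' by construction.
#'
#' @param X n x 2 matrix.
#' @inheritParams truncated_bvn_means
#' @param base_cov Covariance of the untruncated generating normal.
#' @export
recentre_to_truncated_means <- function(X, box, base_cov) {
  stopifnot(is.matrix(X), ncol(X) == 2L, all(is.finite(X)))
  m <- truncated_bvn_means(box, base_cov)
  sweep(sweep(X, 2L, colMeans(X)), 2L, m, "+")
}

#' Generate item parameters with exact sample moments
#'
#' The three-step generating procedure: (1) draw (discrimination,
#' difficulty) pairs from the box-truncated bivariate normal; (2) rescale to
#' the exact target covariance `Sigma = tau %*% Omega %*% t(tau)`; (3) shift
#' the columns to the true truncated-normal marginal means. Whole sets whose
#' parameters leave the admissible ranges `0.5 < alpha < 3.5`,
#' `-4 < beta < 4` are redrawn (at most `max_redraws` times).
#'
#' By default generation happens on the natural (alpha, beta) scale, as the
#' truncation limits imply; `scale = "log"` generates on the
#' (log alpha, beta) scale instead and exponentiates the first column (the
#' exact-moment guarantee then holds for log alpha).
#'
#' @param cond A [generating_condition()].
#' @param box A [truncation_box()].
#' @param scale `"natural"` (default) or `"log"`.
#' @param max_redraws Cap on range-violation redraws (default 100).
#' @param enforce_range Enforce the admissible ranges (default TRUE).
#' @return List with `items` (an [item_parameters()]), `sigma` (the true
#'   2 x 2 covariance) and `n_redraws`.
#' @export
generate_item_parameters <- function(cond, box = truncation_box(),
                                     scale = c("natural", "log"),
                                     max_redraws = 100L, enforce_range = TRUE) {
  scale <- match.arg(scale)
  stopifnot(inherits(cond, "generating_condition"))
  Sigma <- condition_sigma(cond)
  for (attempt in 0:max_redraws) {
    Z <- draw_truncated_bvn(cond$n_items, box, Sigma)
    X <- exact_covariance_rescale(Z, Sigma)
    X <- recentre_to_truncated_means(X, box, Sigma)
    alpha <- if (scale == "log") exp(X[, 1L]) else X[, 1L]
    beta <- X[, 2L]
    ok <- all(alpha > 0.5 & alpha < 3.5) && all(beta > -4 & beta < 4)
    if (!enforce_range || ok)
      return(list(items = item_parameters(alpha, beta), sigma = Sigma,
                  n_redraws = attempt))
  }
  stop(sprintf("item parameters left the admissible ranges in all %d redraws",
               max_redraws + 1L), call. = FALSE)
}

#' Draw standard-normal person abilities
#'
#' @param n Number of persons.
#' @export
generate_abilities <- function(n) {
  stopifnot(n >= 1L)
  stats::rnorm(n)
}

#' Draw Bernoulli responses under the 2PL
#'
#' @param theta Person abilities.
#' @param items An [item_parameters()] object.
#' @return A [response_matrix()] of independent Bernoulli draws with
#'   probabilities `response_probability(theta_j, alpha_i, beta_i)`.
#' @export
generate_responses <- function(theta, items) {
  stopifnot(inherits(items, "item_parameters"))
  N <- length(theta); I <- length(items$alpha)
  p <- response_probability(rep(theta, times = I),
                            rep(items$alpha, each = N),
                            rep(items$beta, each = N))
  response_matrix(matrix(stats::rbinom(N * I, 1L, p), N, I))
}

#' Generate one replication of a design condition
#'
#' Seeds the RNG from the condition, draws fresh item parameters, abilities
#' and responses, and returns them together with the generating truth.
#'
#' @inheritParams generate_item_parameters
#' @return An object of class `generated_dataset`: list with `responses`,
#'   `items`, `theta`, `sigma`, `condition`.
#' @export
generate_dataset <- function(cond, box = truncation_box(),
                             scale = c("natural", "log")) {
  scale <- match.arg(scale)
  set.seed(cond$seed)
  gen <- generate_item_parameters(cond, box, scale)
  theta <- generate_abilities(cond$n_persons)
  responses <- generate_responses(theta, gen$items)
  structure(list(responses = responses, items = gen$items, theta = theta,
                 sigma = gen$sigma, condition = cond),
            class = "generated_dataset")
}

#' @export
print.generated_dataset <- function(x, ...) {
  cat(sprintf("<generated_dataset> N=%d persons, k=%d items (tau=%.2f/%.2f, rho=%.1f, seed=%d)\n",
              x$condition$n_persons, x$condition$n_items,
              x$condition$tau_pair[1L], x$condition$tau_pair[2L],
              x$condition$rho, x$condition$seed))
  invisible(x)
}
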