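# Bock-Aitkin marginal maximum likelihood for the 2PL: quadrature over the
# ability distribution, per-item weighted logistic maximization in the
# slope/intercept parameterization, plus the inadmissibility screen used by
# the simulation harness.

#' EM settings for the MML fit
#'
#' @param n_quadrature Number of quadrature points (>= 11, default 41).
#' @param grid_range Ability range covered by the equally spaced grid
#'   (default c(-6, 6)); the grid carries standard-normal density weights.
#' @param quadrature `"rectangular"` (Bock-Aitkin convention, default) or
#'   `"gauss_hermite"`.
#' @param max_iterations EM iteration cap (default 500).
#' @param tolerance Convergence tolerance on the change in marginal
#'   log-likelihood (default 1e-6).
#' @export
em_settings <- function(n_quadrature = 41L, grid_range = c(-6, 6),
                        quadrature = c("rectangular", "gauss_hermite"),
                        max_iterations = 500L, tolerance = 1e-6) {
  quadrature <- match.arg(quadrature)
  stopifnot(n_quadrature >= 11L, tolerance > 0, max_iterations >= 1L,
            grid_range[1L] < grid_range[2L])
  structure(list(n_quadrature = as.integer(n_quadrature),
                 grid_range = grid_range, quadrature = quadrature,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "em_settings")
}

.quad_grid <- function(settings) {
  if (settings$quadrature == "rectangular") {
    nodes <- seq(settings$grid_range[1L], settings$grid_range[2L],
                 length.out = settings$n_quadrature)
    w <- stats::dnorm(nodes)
    list(nodes = nodes, weights = w / sum(w))
  } else {
    # Gauss-Hermite nodes/weights via the Golub-Welsch eigendecomposition,
    # rescaled to the standard-normal measure
    n <- settings$n_quadrature
    J <- matrix(0, n, n)
    off <- sqrt(seq_len(n - 1L) / 2)
    J[cbind(seq_len(n - 1L), 2:n)] <- off
    J[cbind(2:n, seq_len(n - 1L))] <- off
    e <- eigen(J, symmetric = TRUE)
    nodes <- e$values * sqrt(2)
    w <- e$vectors[1L, ]^2
    ord <- order(nodes)
    list(nodes = nodes[ord], weights = w[ord] / sum(w))
  }
}

# per-item weighted logistic Newton-Raphson in slope/intercept form:
# logit p_q = a * node_q + c, expected counts r_q of n_q
.mstep_item <- function(nodes, r, n, a0, c0, penalty = NULL, max_steps = 50L) {
  par <- c(a0, c0)
  X <- cbind(nodes, 1)
  for (s in seq_len(max_steps)) {
    eta <- X %*% par
    p <- stats::plogis(eta)
    g <- crossprod(X, r - n * p)
    wv <- n * p * (1 - p)
    H <- -crossprod(X * as.numeric(wv), X)
    if (!is.null(penalty)) {
      # lognormal(mu, sd) penalty on the slope: -((log a - mu)^2 / (2 sd^2)) - log a
      av <- max(par[1L], 1e-8)
      g[1L] <- g[1L] - (log(av) - penalty$mu) / (penalty$sd^2 * av) - 1 / av
      H[1L, 1L] <- H[1L, 1L] - 1 / (penalty$sd^2 * av^2)
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new <- par - as.numeric(step)
    new <- pmin(pmax(new, -60), 60)  # keep the boundary-pattern runaway finite
    if (max(abs(new - par)) < 1e-10) { par <- new; break }
    par <- new
  }
  par
}

#' Fit the 2PL by Bock-Aitkin marginal maximum likelihood
#'
#' EM alternation of expected response counts on the quadrature grid
#' (E-step) and per-item weighted logistic Newton-Raphson in the
#' slope/intercept parameterization (M-step). The marginal log-likelihood is
#' non-decreasing across iterations. Items answered all-correct or all-wrong
#' are flagged as boundary patterns; the fit continues but is screened as
#' inadmissible.
#'
#' @param y A [response_matrix()] (or plain 0/1/NA matrix).
#' @param settings An [em_settings()].
#' @param slope_penalty Optional list of per-item lognormal penalties on the
#'   slope, e.g. `list("3" = list(mu = 0, sd = 0.5))`, keyed by item index.
#' @param alpha_cap,beta_cap Admissibility caps passed to
#'   [screen_admissible()].
#' @return An object of class `mml_result`: slope/intercept estimates,
#'   classical [item_parameters()] (where defined), person EAP scores,
#'   convergence and admissibility flags, the log-likelihood trace, and
#'   per-item boundary flags.
#' @export
fit_mml <- function(y, settings = em_settings(), slope_penalty = NULL,
                    alpha_cap = 10, beta_cap = 10) {
  if (!inherits(y, "response_matrix")) y <- response_matrix(y)
  Y <- y$y
  N <- nrow(Y); I <- ncol(Y)
  grid <- .quad_grid(settings)
  Q <- length(grid$nodes)
  obs <- !is.na(Y)
  Y0 <- Y; Y0[!obs] <- 0L

  boundary <- vapply(seq_len(I), function(i) {
    v <- Y[obs[, i], i]
    length(unique(v)) < 2L
  }, logical(1))

  a <- rep(1, I); cc <- rep(0, I)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(settings$max_iterations)) {
    # E-step: person posteriors over the grid
    eta <- outer(grid$nodes, a) + matrix(cc, Q, I, byrow = TRUE)  # Q x I
    lp <- stats::plogis(eta)
    llog <- log(pmax(lp, 1e-300)); l1og <- log(pmax(1 - lp, 1e-300))
    # log L_j(q) over observed cells: N x Q
    ll_pq <- tcrossprod(Y0 * obs, llog) + tcrossprod((1 - Y0) * obs, l1og)
    lw <- sweep(ll_pq, 2L, log(grid$weights), "+")
    m <- apply(lw, 1L, max)
    W <- exp(lw - m)
    marg <- rowSums(W)
    ll <- sum(log(marg) + m)
    P <- W / marg                      # N x Q posterior weights
    trace <- c(trace, ll)
    if (iter > 1L && abs(ll - trace[iter - 1L]) < settings$tolerance) {
      converged <- TRUE
      break
    }
    # expected counts per item (missing cells excluded)
    for (i in seq_len(I)) {
      oi <- obs[, i]
      n_q <- colSums(P[oi, , drop = FALSE])
      r_q <- colSums(P[oi & Y0[, i] == 1L, , drop = FALSE])
      pen <- slope_penalty[[as.character(i)]]
      par <- .mstep_item(grid$nodes, r_q, n_q, a[i], cc[i], pen)
      a[i] <- par[1L]; cc[i] <- par[2L]
    }
  }

  si <- slope_intercept(a, cc)
  cl <- slope_intercept_to_classical(si)
  res <- structure(list(slope_intercept = si, items = cl$items,
                        item_defined = cl$defined, boundary = boundary,
                        converged = converged, loglik_trace = trace,
                        settings = settings),
                   class = "mml_result")
  res$admissible <- screen_admissible(res, alpha_cap = alpha_cap,
                                      beta_cap = beta_cap)
  res$theta <- if (!is.null(res$items) && res$admissible)
    eap_scores(y, res$items, grid) else .eap_raw(Y, a, cc, grid)
  res
}

#' @export
print.mml_result <- function(x, ...) {
  cat(sprintf("<mml_result> %d items, %s, %s (logLik %.2f after %d EM iterations)\n",
              length(x$slope_intercept$a),
              if (x$converged) "converged" else "NOT converged",
              if (x$admissible) "admissible" else "inadmissible",
              utils::tail(x$loglik_trace, 1L), length(x$loglik_trace)))
  invisible(x)
}

#' Slope/intercept item parameters
#'
#' The parameterization `logit^-1(a * theta + c)` the M-step maximizes.
#'
#' @param a Slopes; `c` intercepts.
#' @export
slope_intercept <- function(a, c) {
  stopifnot(length(a) == length(c), all(is.finite(a)), all(is.finite(c)))
  structure(list(a = as.numeric(a), c = as.numeric(c)), class = "slope_intercept")
}

#' Transform slope/intercept to the classical parameterization
#'
#' `alpha = a`, `beta = -c / a` (from `a * (theta - beta) = a * theta + c`).
#' Items with `a = 0` are undefined and flagged rather than raised; sets
#' containing nonpositive slopes yield `items = NULL` (the classical
#' container requires positive discriminations) while still reporting the
#' raw transformed values.
#'
#' @param p A [slope_intercept()] object.
#' @return List with `alpha`, `beta` (raw transform, NA where undefined),
#'   `defined` (per-item flag) and `items` (an [item_parameters()] when all
#'   discriminations are positive, otherwise NULL).
#' @export
slope_intercept_to_classical <- function(p) {
  stopifnot(inherits(p, "slope_intercept"))
  defined <- p$a != 0
  alpha <- p$a
  beta <- ifelse(defined, -p$c / p$a, NA_real_)
  items <- if (all(defined) && all(alpha > 0)) item_parameters(alpha, beta) else NULL
  list(alpha = alpha, beta = beta, defined = defined, items = items)
}

#' Admissibility screen for an MML solution
#'
#' FALSE when the EM did not converge, any classical discrimination is
#' nonpositive or undefined, or any estimate exceeds the caps
#' (`alpha > alpha_cap` or `|beta| > beta_cap`); boundary-pattern items
#' (all-correct / all-wrong) are inadmissible as well.
#'
#' @param result An `mml_result` (or a list with the same fields).
#' @param alpha_cap,beta_cap Screening caps (defaults 10 and 10).
#' @export
screen_admissible <- function(result, alpha_cap = 10, beta_cap = 10) {
  if (!isTRUE(result$converged)) return(FALSE)
  if (any(result$boundary)) return(FALSE)
  a <- result$slope_intercept$a
  b <- -result$slope_intercept$c / a
  if (any(!result$item_defined) || any(a <= 0)) return(FALSE)
  all(a <= alpha_cap) && all(abs(b) <= beta_cap)
}

#' Expected a posteriori ability scores
#'
#' Posterior mean of theta per person on the quadrature grid under the
#' standard-normal population prior, for fixed item parameters.
#'
#' @param y A [response_matrix()].
#' @param items An [item_parameters()] object.
#' @param grid Optional list with `nodes` and `weights`; defaults to the
#'   41-point rectangular grid on \[-6, 6\].
#' @return Numeric vector of EAP scores, one per person.
#' @export
eap_scores <- function(y, items, grid = NULL) {
  if (!inherits(y, "response_matrix")) y <- response_matrix(y)
  stopifnot(inherits(items, "item_parameters"))
  grid <- grid %||% .quad_grid(em_settings())
  .eap_raw(y$y, items$alpha, -items$alpha * items$beta, grid)
}

# EAP on slope/intercept values (works even for inadmissible solutions)
.eap_raw <- function(Y, a, cc, grid) {
  Q <- length(grid$nodes); I <- length(a)
  obs <- !is.na(Y)
  Y0 <- Y; Y0[!obs] <- 0L
  eta <- outer(grid$nodes, a) + matrix(cc, Q, I, byrow = TRUE)
  lp <- stats::plogis(eta)
  llog <- log(pmax(lp, 1e-300)); l1og <- log(pmax(1 - lp, 1e-300))
  lw <- sweep(tcrossprod(Y0 * obs, llog) + tcrossprod((1 - Y0) * obs, l1og),
              2L, log(grid$weights), "+")
  m <- apply(lw, 1L, max)
  W <- exp(lw - m)
  as.numeric((W %*% grid$nodes) / rowSums(W))
}
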