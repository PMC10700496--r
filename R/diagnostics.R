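#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance formulation:
#' `R = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the chain means times `n`.
#' The split-chain variant (each chain halved before the computation) is
#' available via `split = TRUE`. Chains that are all constant (zero within-
#' and between-chain variance) return exactly 1.
#'
#' @param chains A list of (or matrix with columns as) per-chain draw
#'   vectors for one parameter; at least 2 chains of at least 10 draws.
#' @param split Use the split-chain variant (default FALSE).
#' @return The potential scale reduction factor.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(i) chains[, i])
  if (length(chains) < 2L) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 10L) stop("need at least 10 draws per chain", call. = FALSE)
  if (split) {
    h <- n %/% 2L
    chains <- c(lapply(chains, function(x) x[seq_len(h)]),
                lapply(chains, function(x) x[(length(x) - h + 1L):length(x)]))
    n <- h
  }
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) return(1)
  means <- vapply(chains, mean, numeric(1))
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest density interval of a sample
#'
#' Shortest contiguous window of the sorted sample containing
#' `ceiling(mass * n)` points; width ties are broken towards the smaller
#' lower bound.
#'
#' @param samples Numeric vector, length >= 2.
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("`mass` must lie in (0, 1)", call. = FALSE)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- sort(samples)
  w <- ceiling(mass * n)
  if (w >= n) return(c(lower = s[1L], upper = s[n]))
  widths <- s[w:n] - s[1L:(n - w + 1L)]
  k <- which.min(widths)  # which.min returns the first (smallest start) tie
  c(lower = s[k], upper = s[k + w - 1L])
}

#' Effective sample size
#'
#' Spectral-density estimator as implemented by `coda::effectiveSize`,
#' applied to the pooled post-burn-in draws.
#'
#' @param chains List of per-chain draw vectors, or a single numeric vector.
#' @export
effective_size <- function(chains) {
  if (is.list(chains)) {
    sum(vapply(chains, function(x) unname(coda::effectiveSize(x)), numeric(1)))
  } else {
    unname(coda::effectiveSize(chains))
  }
}

#' Convergence check at the study's threshold
#'
#' TRUE iff every monitored parameter's potential scale reduction factor is
#' strictly below the threshold (default 1.05; a value of exactly 1.05 fails).
#'
#' @param fit A [fit_bayes()] result, or a numeric vector of R-hat values.
#' @param threshold Strict upper bound (default 1.05).
#' @export
check_convergence <- function(fit, threshold = 1.05) {
  rhats <- if (inherits(fit, "fit_result")) {
    s <- fit$summary
    s$rhat[s$monitored]
  } else {
    as.numeric(fit)
  }
  rhats <- rhats[!is.na(rhats)]
  length(rhats) > 0L && all(rhats < threshold)
}
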