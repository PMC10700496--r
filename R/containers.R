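# Small validated containers shared by all modules.

#' Classical 2PL item parameters
#'
#' @param alpha Item discriminations, strictly positive, length I.
#' @param beta Item difficulties (logit scale), length I.
#' @return An object of class `item_parameters`.
#' @export
item_parameters <- function(alpha, beta) {
  if (length(alpha) != length(beta))
    stop("`alpha` and `beta` must have equal length", call. = FALSE)
  if (anyNA(alpha) || anyNA(beta) || any(!is.finite(alpha)) || any(!is.finite(beta)))
    stop("item parameters must be finite", call. = FALSE)
  if (any(alpha <= 0))
    stop("discriminations `alpha` must be strictly positive", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "item_parameters")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("<item_parameters> %d items\n", length(x$alpha)))
  cat(sprintf("  alpha: mean %.3f sd %.3f | beta: mean %.3f sd %.3f\n",
              mean(x$alpha), stats::sd(x$alpha), mean(x$beta), stats::sd(x$beta)))
  invisible(x)
}

#' Hyperparameters of the hierarchical item prior
#'
#' @param mu_alpha,mu_beta Grand means of the log-discriminations and
#'   difficulties.
#' @param tau_alpha,tau_beta Positive scales of the log-discriminations and
#'   difficulties.
#' @param L_Omega 2 x 2 lower-triangular correlation Cholesky factor.
#' @export
hyper_parameters <- function(mu_alpha, mu_beta, tau_alpha, tau_beta, L_Omega) {
  vals <- c(mu_alpha, mu_beta, tau_alpha, tau_beta)
  if (length(vals) != 4L || anyNA(vals) || any(!is.finite(vals)))
    stop("hyperparameters must be finite scalars", call. = FALSE)
  if (tau_alpha <= 0 || tau_beta <= 0)
    stop("`tau_alpha` and `tau_beta` must be strictly positive", call. = FALSE)
  .check_corr_chol(L_Omega)
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta, tau_alpha = tau_alpha,
                 tau_beta = tau_beta, L_Omega = L_Omega),
            class = "hyper_parameters")
}

#' Actively sampled state of the non-centered hierarchical 2PL
#'
#' Holds the parameters the sampler actually moves: the 2 x I matrix of item
#' z-scores, the grand means, the correlation Cholesky factor, the person
#' abilities, and either the bounded auxiliaries for the variance components
#' (half-Cauchy / Exponential configurations) or the components themselves
#' (inverse-Gamma configuration).
#'
#' @param xi_tilde 2 x I matrix of z-scores (row 1: log-discrimination, row
#'   2: difficulty direction).
#' @param mu_alpha,mu_beta Grand means.
#' @param L_Omega 2 x 2 lower-triangular correlation Cholesky factor.
#' @param theta Person abilities (may be length zero when only items are of
#'   interest).
#' @param tau_alpha_unif,tau_beta_unif Bounded auxiliaries; supply for
#'   half-Cauchy (support (0, pi/2)) or Exponential (support (0, 1))
#'   configurations.
#' @param tau_alpha,tau_beta Directly parameterized positive scales; supply
#'   for inverse-Gamma configurations.
#' @export
noncentered_state <- function(xi_tilde, mu_alpha, mu_beta, L_Omega,
                              theta = numeric(0),
                              tau_alpha_unif = NULL, tau_beta_unif = NULL,
                              tau_alpha = NULL, tau_beta = NULL) {
  if (!is.matrix(xi_tilde) || nrow(xi_tilde) != 2L || anyNA(xi_tilde) ||
      any(!is.finite(xi_tilde)))
    stop("`xi_tilde` must be a finite 2 x I matrix", call. = FALSE)
  .check_corr_chol(L_Omega)
  if (anyNA(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite", call. = FALSE)
  has_aux <- !is.null(tau_alpha_unif) && !is.null(tau_beta_unif)
  has_tau <- !is.null(tau_alpha) && !is.null(tau_beta)
  if (!has_aux && !has_tau)
    stop("supply either the bounded auxiliaries or tau_alpha/tau_beta",
         call. = FALSE)
  if (has_tau && (tau_alpha <= 0 || tau_beta <= 0))
    stop("`tau_alpha` and `tau_beta` must be strictly positive", call. = FALSE)
  structure(list(xi_tilde = xi_tilde, mu_alpha = mu_alpha, mu_beta = mu_beta,
                 L_Omega = L_Omega, theta = as.numeric(theta),
                 tau_alpha_unif = tau_alpha_unif, tau_beta_unif = tau_beta_unif,
                 tau_alpha = tau_alpha, tau_beta = tau_beta),
            class = "noncentered_state")
}

#' Dichotomous person x item response matrix
#'
#' @param y Matrix with entries 0, 1 or NA (missing), persons as rows.
#' @param person_ids,item_ids Optional labels; defaults `P1..PN` / `I1..Ik`.
#' @param require_complete_margins Require at least one observed response per
#'   person and per item (default TRUE).
#' @export
response_matrix <- function(y, person_ids = NULL, item_ids = NULL,
                            require_complete_margins = TRUE) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  ok <- is.na(y) | y == 0L | y == 1L
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary response at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (require_complete_margins) {
    if (any(rowSums(!is.na(y)) == 0L))
      stop("every person must have at least one observed response", call. = FALSE)
    if (any(colSums(!is.na(y)) == 0L))
      stop("every item must have at least one observed response", call. = FALSE)
  }
  person_ids <- person_ids %||% paste0("P", seq_len(nrow(y)))
  item_ids <- item_ids %||% paste0("I", seq_len(ncol(y)))
  stopifnot(length(person_ids) == nrow(y), length(item_ids) == ncol(y))
  dimnames(y) <- list(person_ids, item_ids)
  structure(list(y = y, person_ids = person_ids, item_ids = item_ids),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %d missing\n",
              nrow(x$y), ncol(x$y), sum(is.na(x$y))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$y)

`%||%` <- function(a, b) if (is.null(a)) b else a
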