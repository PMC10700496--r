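#' MCMC chain protocol
#'
#' Defaults follow the study protocol: three chains of 4000 iterations with
#' 1000 burn-in cycles and dispersed random starting values per chain.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_iterations Iterations per chain (burn-in included).
#' @param n_burnin Burn-in iterations discarded from each chain; proposal
#'   adaptation happens only during burn-in.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param init_strategy Starting-value policy; only `"dispersed"` (random
#'   draws around the priors, different per chain) is implemented.
#' @export
chain_spec <- function(n_chains = 3L, n_iterations = 4000L, n_burnin = 1000L,
                       seed = 1L, init_strategy = "dispersed") {
  stopifnot(n_chains >= 2L, n_burnin >= 1L, n_burnin < n_iterations)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), seed = as.integer(seed),
                 init_strategy = init_strategy),
            class = "chain_spec")
}

.chain_seed <- function(spec, chain) {
  as.integer((as.double(spec$seed) + 1000003 * chain) %% 2147483647)
}

.family_code <- function(config) {
  switch(config$family,
         half_cauchy = 0L,
         exponential = 1L,
         inverse_gamma = if (identical(config$params$on, "tau_sq")) 3L else 2L,
         stop("unsupported family for the non-centered model", call. = FALSE))
}

.param_names <- function(N, I) {
  c(sprintf("alpha[%d]", seq_len(I)), sprintf("beta[%d]", seq_len(I)),
    sprintf("theta[%d]", seq_len(N)),
    "mu_alpha", "mu_beta", "tau_alpha", "tau_beta", "rho")
}

# dispersed random starting values, per model
.init_state <- function(model, config, N, I, fix_items = NULL) {
  if (model == "hier2pl") {
    va_vb <- switch(config$family,
      half_cauchy = stats::runif(2L, 0.05, 1.0),
      exponential = stats::runif(2L, 0.30, 0.95),
      inverse_gamma = stats::rnorm(2L, log(0.5), 0.5))
    list(theta = stats::rnorm(N, 0, 0.5), xt1 = stats::rnorm(I, 0, 0.5),
         xt2 = stats::rnorm(I, 0, 0.5), mu_a = stats::rnorm(1L, 0, 0.4),
         mu_b = stats::rnorm(1L, 0, 0.5), va = va_vb[1L], vb = va_vb[2L],
         r = stats::runif(1L, -0.3, 0.3))
  } else if (model == "iw2pl") {
    list(theta = stats::rnorm(N, 0, 0.5), log_alpha = stats::rnorm(I, 0, 0.3),
         beta = stats::rnorm(I, 0, 0.5), mu_a = stats::rnorm(1L, 0, 0.4),
         mu_b = stats::rnorm(1L, 0, 0.5), s11 = stats::runif(1L, 0.05, 0.4),
         s12 = 0, s22 = stats::runif(1L, 0.2, 1.2))
  } else {
    if (!is.null(fix_items))
      list(theta = stats::rnorm(N, 0, 0.5), log_alpha = log(fix_items$alpha),
           beta = fix_items$beta)
    else
      list(theta = stats::rnorm(N, 0, 0.5), log_alpha = stats::rnorm(I, 0, 0.3),
           beta = stats::rnorm(I, 0, 0.5))
  }
}

#' Fit a Bayesian 2PL variant by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs engine under the chain protocol
#' in `chains`, reconstructs the classical item parameterization per draw
#' (the non-centered model samples z-scores and auxiliaries only), and
#' returns convergence-checked posterior summaries.
#'
#' Monitored for the convergence flag are all item discriminations and
#' difficulties plus the grand means and variance components (not the person
#' abilities); a fit converged when every monitored potential scale
#' reduction factor is strictly below 1.05.
#'
#' Initialization failures are retried up to 3 times with fresh dispersed
#' starting values; a sampler failure yields a flagged non-convergent result
#' rather than an error.
#'
#' @param y A [response_matrix()] (or plain 0/1/NA matrix).
#' @param model `"hier2pl"` (non-centered separation-strategy hierarchical
#'   2PL), `"iw2pl"` (centered, inverse-Wishart covariance prior) or
#'   `"simple2pl"` (nonhierarchical).
#' @param config A [hyperprior_config()]; required for `"hier2pl"`.
#' @param chains A [chain_spec()].
#' @param scale_reading Reading of the N(0, 2) priors: `"sd"` (default) or
#'   `"variance"`.
#' @param point_estimate Posterior `"mean"` (default) or `"median"`,
#'   computed on the classical scale (discriminations averaged after
#'   exponentiation).
#' @param fix_items Optional [item_parameters()]; with `model = "simple2pl"`
#'   holds the item parameters fixed and samples abilities only.
#' @param keep_draws Keep the per-chain draw matrices in the result
#'   (default TRUE).
#' @param hdi_mass Mass of the highest density intervals (default 0.95).
#' @param compute_ess Compute effective sample sizes (default TRUE; the
#'   spectral estimator dominates summary cost for large person counts, so
#'   study runs may disable it — convergence checks use R-hat only).
#' @return An object of class `fit_result`: list with `summary` (data.frame
#'   with parameter, mean, sd, hdi_low, hdi_high, rhat, ess, monitored),
#'   `converged`, `model`, `config`, `chains`, `runtime_s`, and (optionally)
#'   `draws`, a list of per-chain matrices (iterations x parameters).
#' @export
fit_bayes <- function(y, model = c("hier2pl", "iw2pl", "simple2pl"),
                      config = NULL, chains = chain_spec(),
                      scale_reading = c("sd", "variance"),
                      point_estimate = c("mean", "median"), fix_items = NULL,
                      keep_draws = TRUE, hdi_mass = 0.95, compute_ess = TRUE) {
  model <- match.arg(model)
  scale_reading <- match.arg(scale_reading)
  point_estimate <- match.arg(point_estimate)
  if (!inherits(y, "response_matrix")) y <- response_matrix(y)
  stopifnot(inherits(chains, "chain_spec"))
  if (model == "hier2pl") {
    if (is.null(config)) config <- hyperprior_config("exponential", "WI2")
    if (config$family == "inverse_wishart")
      stop("use model = \"iw2pl\" for the inverse-Wishart comparator", call. = FALSE)
  }
  if (model == "iw2pl" && is.null(config)) config <- hyperprior_config("inverse_wishart")
  N <- nrow(y$y); I <- ncol(y$y)
  mu_b_sd <- if (scale_reading == "sd") 2 else sqrt(2)
  Y <- y$y
  t0 <- proc.time()[["elapsed"]]

  draws <- vector("list", chains$n_chains)
  failed <- FALSE
  for (ch in seq_len(chains$n_chains)) {
    res <- NULL
    for (attempt in 1:3) {
      set.seed(.chain_seed(chains, ch) + (attempt - 1L) * 97L)
      init <- .init_state(model, config, N, I, fix_items)
      res <- tryCatch(
        switch(model,
          hier2pl = .cpp_sample_hier2pl(Y, .family_code(config),
            switch(config$family, half_cauchy = config$params$scale,
                   exponential = 1 / config$params$inverse_scale,
                   inverse_gamma = config$params$a),
            if (config$family == "inverse_gamma") config$params$b else 0,
            config$eta, mu_b_sd, chains$n_iterations, chains$n_burnin, init),
          iw2pl = .cpp_sample_iw2pl(Y, config$params$df, config$params$scale_matrix,
            mu_b_sd, chains$n_iterations, chains$n_burnin, init),
          simple2pl = .cpp_sample_simple2pl(Y, mu_b_sd, !is.null(fix_items),
            chains$n_iterations, chains$n_burnin, init)),
        error = function(e) NULL)
      if (!is.null(res) && all(is.finite(res[, seq_len(2L * I)]))) break
      res <- NULL
    }
    if (is.null(res)) { failed <- TRUE; break }
    colnames(res) <- .param_names(N, I)
    draws[[ch]] <- res
  }

  runtime <- proc.time()[["elapsed"]] - t0
  if (failed) {
    return(structure(list(summary = NULL, converged = FALSE, model = model,
                          config = config, chains = chains, runtime_s = runtime,
                          failure = "sampler failed after 3 initialization retries"),
                     class = "fit_result"))
  }

  pn <- colnames(draws[[1L]])
  keep <- vapply(pn, function(p) !all(is.na(draws[[1L]][, p])), logical(1))
  pn <- pn[keep]
  monitored <- grepl("^(alpha|beta)\\[", pn) | pn %in%
    c("mu_alpha", "mu_beta", "tau_alpha", "tau_beta")
  summ <- do.call(rbind, lapply(seq_along(pn), function(k) {
    p <- pn[k]
    per_chain <- lapply(draws, function(d) d[, p])
    pooled <- unlist(per_chain, use.names = FALSE)
    h <- hdi(pooled, hdi_mass)
    data.frame(parameter = p,
               mean = if (point_estimate == "mean") mean(pooled) else stats::median(pooled),
               sd = stats::sd(pooled),
               hdi_low = h[[1L]], hdi_high = h[[2L]],
               rhat = gelman_rubin(per_chain),
               ess = if (compute_ess) effective_size(per_chain) else NA_real_,
               monitored = monitored[k],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 converged = check_convergence(summ$rhat[summ$monitored]),
                 model = model, config = config, chains = chains,
                 runtime_s = runtime,
                 draws = if (keep_draws) draws else NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s%s, %s\n", x$model,
              if (!is.null(x$config) && !is.null(x$config$label))
                paste0(" (", x$config$family, "/", x$config$label, ")") else "",
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$summary)) {
    hyper <- x$summary[!grepl("\\[", x$summary$parameter), ]
    if (nrow(hyper)) print(hyper[, c("parameter", "mean", "sd", "rhat", "ess")],
                           row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Extract posterior point estimates of the item parameters
#'
#' @param fit A converged (or not) `fit_result` with a summary table.
#' @return An [item_parameters()] object, or NULL when the fit failed.
#' @export
estimated_items <- function(fit) {
  if (is.null(fit$summary)) return(NULL)
  s <- fit$summary
  a <- s$mean[grepl("^alpha\\[", s$parameter)]
  b <- s$mean[grepl("^beta\\[", s$parameter)]
  item_parameters(a, b)
}

#' Extract posterior point estimates of the person abilities
#'
#' @inheritParams estimated_items
#' @export
estimated_theta <- function(fit) {
  if (is.null(fit$summary)) return(NULL)
  fit$summary$mean[grepl("^theta\\[", fit$summary$parameter)]
}

#' Extract posterior point estimates of the variance components
#'
#' @inheritParams estimated_items
#' @return Named vector with `tau_alpha`, `tau_beta` (NA for models without
#'   variance components).
#' @export
estimated_tau <- function(fit) {
  if (is.null(fit$summary)) return(c(tau_alpha = NA_real_, tau_beta = NA_real_))
  s <- fit$summary
  get1 <- function(p) if (p %in% s$parameter) s$mean[s$parameter == p] else NA_real_
  c(tau_alpha = get1("tau_alpha"), tau_beta = get1("tau_beta"))
}
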