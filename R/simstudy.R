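# Fully crossed design, replication loop, discard rules and bias/RMSE
# evaluation of the parameter-recovery study.

#' Enumerate the fully crossed simulation design
#'
#' Defaults reproduce the study grid: 6 sample sizes x 2 test lengths x 3
#' variance-component pairs x 2 correlations x 12 hyperprior cells (3
#' families with 4 specifications each) = 864 cells.
#'
#' @param sample_sizes,test_lengths Factor levels.
#' @param tau_pairs List of length-2 variance-component (SD) pairs.
#' @param rhos Item-parameter correlations.
#' @param families,specs Hyperprior families and catalogue labels crossed
#'   into the hyperprior factor.
#' @param replications Replications per cell (default 100).
#' @return A data.frame of class `design_grid`, one row per cell, with a
#'   `cell` identifier column.
#' @export
build_design_grid <- function(sample_sizes = c(50L, 75L, 100L, 150L, 200L, 500L),
                              test_lengths = c(25L, 50L),
                              tau_pairs = list(c(0.10, 0.40), c(0.25, 0.90),
                                               c(0.75, 1.50)),
                              rhos = c(0, 0.3),
                              families = c("half_cauchy", "exponential",
                                           "inverse_gamma"),
                              specs = c("WI1", "WI2", "NI1", "NI2"),
                              replications = 100L) {
  g <- expand.grid(n_persons = sample_sizes, n_items = test_lengths,
                   tau_level = seq_along(tau_pairs), rho = rhos,
                   family = families, spec = specs,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$tau_alpha <- vapply(g$tau_level, function(i) tau_pairs[[i]][1L], numeric(1))
  g$tau_beta <- vapply(g$tau_level, function(i) tau_pairs[[i]][2L], numeric(1))
  g$replications <- as.integer(replications)
  g$cell <- sprintf("N%d_k%d_tau%g-%g_rho%g_%s_%s", g$n_persons, g$n_items,
                    g$tau_alpha, g$tau_beta, g$rho, g$family, g$spec)
  class(g) <- c("design_grid", "data.frame")
  g
}

#' Signed estimation bias
#'
#' @param estimate,truth Finite numerics (recycled).
#' @return `estimate - truth`.
#' @export
bias <- function(estimate, truth) {
  if (any(!is.finite(estimate)) || any(!is.finite(truth)))
    stop("`estimate` and `truth` must be finite", call. = FALSE)
  estimate - truth
}

#' Root mean squared error over replications
#'
#' `sqrt(sum((estimate - truth)^2) / R)` with `R` the number of
#' replications.
#'
#' @param estimates,truths Equal-length vectors over replications.
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("`estimates` and `truths` must have equal length", call. = FALSE)
  if (length(estimates) < 1L) stop("need at least one replication", call. = FALSE)
  sqrt(mean((estimates - truths)^2))
}

#' Aggregate item-parameter recovery across replications
#'
#' Bias: averaged across items within each replication, then across
#' replications. RMSE: computed per item over replications, then averaged
#' across items. (Scalar quantities such as variance components aggregate
#' directly over replications.)
#'
#' @param estimates R x I matrix (replications x items) of estimates.
#' @param truths R x I matrix of the matching true values.
#' @return List with `bias` and `rmse`.
#' @export
aggregate_item_parameters <- function(estimates, truths) {
  estimates <- as.matrix(estimates); truths <- as.matrix(truths)
  if (!all(dim(estimates) == dim(truths)))
    stop("`estimates` and `truths` must have identical dimensions", call. = FALSE)
  if (nrow(estimates) < 1L) stop("no usable replications", call. = FALSE)
  dev <- estimates - truths
  list(bias = mean(rowMeans(dev)),
       rmse = mean(sqrt(colMeans(dev^2))))
}

#' Apply the study's discard rules to a set of replication fits
#'
#' Bayesian fits with any monitored potential scale reduction factor at or
#' above 1.05 and MML fits screened inadmissible are removed; they count
#' towards the per-cell non-convergence / inadmissibility rates but never
#' towards bias or RMSE.
#'
#' @param fits List of `fit_result` and/or `mml_result` objects.
#' @return List with `usable` (retained fits), `keep` (logical index),
#'   `nonconvergence_rate` (Bayesian) and `inadmissible_rate` (MML).
#' @export
apply_discard_rules <- function(fits) {
  is_mml <- vapply(fits, inherits, logical(1), what = "mml_result")
  keep <- vapply(seq_along(fits), function(k) {
    if (is_mml[k]) isTRUE(fits[[k]]$admissible) else isTRUE(fits[[k]]$converged)
  }, logical(1))
  nb <- sum(!is_mml); nm <- sum(is_mml)
  list(usable = fits[keep], keep = keep,
       nonconvergence_rate = if (nb) sum(!keep & !is_mml) / nb else NA_real_,
       inadmissible_rate = if (nm) sum(!keep & is_mml) / nm else NA_real_)
}

#' Conditional means across hyperprior specifications
#'
#' For each family and cell grouping, the mean of the four specification
#' values of a summary (the "conditional mean") and each specification's
#' deviation from it. Families with missing specifications are flagged as
#' partial and excluded.
#'
#' @param results Data.frame with columns `family`, `spec`, a value column,
#'   and any grouping columns.
#' @param value Name of the value column (default `"bias"`).
#' @param by Extra grouping columns (default none).
#' @return Data.frame with `conditional_mean` and `deviation` per row, plus
#'   a `partial` flag on incomplete family groups.
#' @export
conditional_mean_table <- function(results, value = "bias", by = character(0)) {
  stopifnot(all(c("family", "spec", value) %in% names(results)))
  key <- interaction(results[c("family", by)], drop = TRUE)
  out <- results
  out$conditional_mean <- NA_real_
  out$deviation <- NA_real_
  out$partial <- FALSE
  for (g in levels(key)) {
    idx <- key == g
    n_spec <- length(unique(results$spec[idx]))
    if (n_spec < 4L) { out$partial[idx] <- TRUE; next }
    cm <- mean(results[[value]][idx])
    out$conditional_mean[idx] <- cm
    out$deviation[idx] <- results[[value]][idx] - cm
  }
  out
}

# deterministic per-cell / per-replication seed derivation (kept < 2^31)
.derive_seed <- function(master, cell_index, rep = 0L) {
  as.integer((as.double(master) + 2654435761 * cell_index + 97003 * rep) %%
               2147483647) + 1L
}

#' Fit one model configuration to a generated dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @param model_cfg List with `model` (`"hier2pl"`, `"iw2pl"`,
#'   `"simple2pl"` or `"mml"`) and, for `hier2pl`, `family` and `spec`.
#' @param chains A [chain_spec()] (Bayesian models).
#' @param seed Seed for the fit's own randomness.
#' @export
fit_model_config <- function(dataset, model_cfg, chains = chain_spec(), seed = 1L) {
  if (model_cfg$model == "mml") return(fit_mml(dataset$responses))
  config <- switch(model_cfg$model,
    hier2pl = hyperprior_config(model_cfg$family, model_cfg$spec),
    iw2pl = hyperprior_config("inverse_wishart"),
    simple2pl = NULL)
  ch <- chains; ch$seed <- as.integer(seed)
  fit_bayes(dataset$responses, model = model_cfg$model, config = config,
            chains = ch, keep_draws = FALSE, compute_ess = FALSE)
}

# recovery summaries of one usable fit against the generating truth
.fit_truth_rows <- function(fit, dataset) {
  items <- if (inherits(fit, "mml_result")) fit$items else estimated_items(fit)
  theta <- if (inherits(fit, "mml_result")) fit$theta else estimated_theta(fit)
  tau <- if (inherits(fit, "mml_result")) c(tau_alpha = NA_real_, tau_beta = NA_real_)
         else estimated_tau(fit)
  list(alpha_est = items$alpha, beta_est = items$beta, theta_est = theta,
       tau_est = tau,
       alpha_true = dataset$items$alpha, beta_true = dataset$items$beta,
       theta_true = dataset$theta,
       tau_true = c(tau_alpha = dataset$condition$tau_pair[1L],
                    tau_beta = dataset$condition$tau_pair[2L]))
}

#' Run (a subset of) the simulation study
#'
#' For every cell of the grid and every replication: generate a dataset,
#' fit each requested model configuration, apply the discard rules, and
#' aggregate the bias/RMSE of the variance components, the item-averaged
#' item parameters, and the person-averaged abilities. Fully reproducible
#' from `master_seed`: every (cell, replication) pair derives its own seed,
#' so cells can be recomputed independently and merged in any order.
#'
#' @param grid A [build_design_grid()] result (subset rows to scale down).
#' @param models List of model configurations; `"hier2pl"` entries default
#'   to the grid row's family/spec, e.g.
#'   `list(list(model = "hier2pl"), list(model = "simple2pl"))`.
#' @param chains A [chain_spec()] applied to the Bayesian fits.
#' @param master_seed Master seed of the seed-splitting scheme.
#' @param checkpoint_path Optional CSV path; one row per
#'   (cell, replication, model) is appended as results arrive, and existing
#'   rows are not recomputed on resume.
#' @param verbose Log progress to stderr.
#' @return A data.frame of class `condition_result`, one row per cell and
#'   model configuration, with bias/RMSE summaries and discard rates.
#' @export
run_study <- function(grid, models = list(list(model = "hier2pl")),
                      chains = chain_spec(), master_seed = 1L,
                      checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "design_grid") || is.data.frame(grid))
  done <- if (!is.null(checkpoint_path) && file.exists(checkpoint_path))
    utils::read.csv(checkpoint_path, stringsAsFactors = FALSE) else NULL
  rep_rows <- list()
  for (ci in seq_len(nrow(grid))) {
    row <- grid[ci, ]
    for (mi in seq_along(models)) {
      mc <- models[[mi]]
      if (mc$model == "hier2pl") {
        mc$family <- mc$family %||% row$family
        mc$spec <- mc$spec %||% row$spec
      }
      mtag <- paste(c(mc$model, mc$family, mc$spec), collapse = "/")
      for (r in seq_len(row$replications)) {
        if (!is.null(done) &&
            any(done$cell == row$cell & done$model == mtag & done$replication == r)) {
          prev <- done[done$cell == row$cell & done$model == mtag &
                         done$replication == r, ]
          rep_rows[[length(rep_rows) + 1L]] <- prev
          next
        }
        seed <- .derive_seed(master_seed, ci, r)
        cond <- generating_condition(row$n_persons, row$n_items,
                                     c(row$tau_alpha, row$tau_beta), row$rho,
                                     seed = seed)
        dataset <- generate_dataset(cond)
        fit <- tryCatch(fit_model_config(dataset, mc, chains, seed = seed + 1L),
                        error = function(e) NULL)
        rec <- .replication_record(row$cell, mtag, r, fit, dataset)
        rep_rows[[length(rep_rows) + 1L]] <- rec
        if (!is.null(checkpoint_path))
          utils::write.table(rec, checkpoint_path, sep = ",", append = file.exists(checkpoint_path),
                             col.names = !file.exists(checkpoint_path),
                             row.names = FALSE)
        if (verbose)
          message(sprintf("[%s] %s rep %d/%d %s", row$cell, mtag, r,
                          row$replications,
                          if (isTRUE(rec$usable)) "ok" else "discarded"))
      }
    }
  }
  reps <- do.call(rbind, rep_rows)
  out <- .aggregate_cells(reps)
  attr(out, "replication_records") <- reps
  class(out) <- c("condition_result", class(out))
  out
}

# flat one-row record of a single (cell, model, replication) fit
.replication_record <- function(cell, mtag, r, fit, dataset) {
  base <- data.frame(cell = cell, model = mtag, replication = r,
                     stringsAsFactors = FALSE)
  failed <- is.null(fit) ||
    (inherits(fit, "fit_result") && is.null(fit$summary))
  usable <- !failed && if (inherits(fit, "mml_result")) isTRUE(fit$admissible)
                       else isTRUE(fit$converged)
  base$is_mml <- !failed && inherits(fit, "mml_result")
  base$usable <- usable
  if (!usable) {
    base[c("bias_alpha", "bias_beta", "bias_theta", "bias_tau_alpha",
           "bias_tau_beta")] <- NA_real_
    base[c("dev_alpha", "dev_beta", "dev_theta")] <- NA_character_
    return(base)
  }
  tr <- .fit_truth_rows(fit, dataset)
  base$bias_alpha <- mean(bias(tr$alpha_est, tr$alpha_true))
  base$bias_beta <- mean(bias(tr$beta_est, tr$beta_true))
  base$bias_theta <- mean(bias(tr$theta_est, tr$theta_true))
  base$bias_tau_alpha <- unname(tr$tau_est["tau_alpha"] - tr$tau_true["tau_alpha"])
  base$bias_tau_beta <- unname(tr$tau_est["tau_beta"] - tr$tau_true["tau_beta"])
  # per-item / per-person deviations feed the per-unit-then-average RMSE rule;
  # packed so checkpoint rows stay flat
  base$dev_alpha <- .pack(bias(tr$alpha_est, tr$alpha_true))
  base$dev_beta <- .pack(bias(tr$beta_est, tr$beta_true))
  base$dev_theta <- .pack(bias(tr$theta_est, tr$theta_true))
  base
}

.pack <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = ";")
.unpack <- function(s) lapply(strsplit(s, ";", fixed = TRUE), as.numeric)

# per-unit RMSE over replications, then averaged across units
.rmse_by_unit <- function(packed) {
  dev <- do.call(rbind, .unpack(packed))
  mean(sqrt(colMeans(dev^2)))
}

.aggregate_cells <- function(reps) {
  key <- interaction(reps$cell, reps$model, drop = TRUE)
  rows <- lapply(levels(key), function(g) {
    sub <- reps[key == g, ]
    use <- sub[sub$usable, ]
    nb <- sum(!sub$is_mml); nm <- sum(sub$is_mml)
    none <- nrow(use) == 0L
    data.frame(
      cell = sub$cell[1L], model = sub$model[1L],
      replications_used = nrow(use),
      nonconvergence_rate = if (nb) sum(!sub$usable & !sub$is_mml) / nb else NA_real_,
      inadmissible_rate = if (nm) sum(!sub$usable & sub$is_mml) / nm else NA_real_,
      bias_alpha = mean(use$bias_alpha), bias_beta = mean(use$bias_beta),
      bias_theta = mean(use$bias_theta),
      bias_tau_alpha = mean(use$bias_tau_alpha),
      bias_tau_beta = mean(use$bias_tau_beta),
      rmse_alpha = if (none) NA_real_ else .rmse_by_unit(use$dev_alpha),
      rmse_beta = if (none) NA_real_ else .rmse_by_unit(use$dev_beta),
      rmse_theta = if (none) NA_real_ else .rmse_by_unit(use$dev_theta),
      rmse_tau_alpha = if (none) NA_real_ else sqrt(mean(use$bias_tau_alpha^2)),
      rmse_tau_beta = if (none) NA_real_ else sqrt(mean(use$bias_tau_beta^2)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
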