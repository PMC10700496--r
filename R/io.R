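# Readers and writers for the delimited interchange formats: response
# matrices (persons x items, header row of item ids, first column person
# id), fit summary tables, and generated-dataset directories.

#' Read a response matrix from delimited text
#'
#' Expected layout: comma-separated (configurable), a header row of item
#' ids, a first column of person ids, and 0/1 entries with a configurable
#' missing marker. Malformed cells are reported with their coordinates.
#'
#' @param path Input file.
#' @param sep Field delimiter (default ",").
#' @param missing Missing-value marker (default "NA").
#' @param header,ids Whether the file carries a header row / id column
#'   (both default TRUE).
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, sep = ",", missing = "NA",
                                 header = TRUE, ids = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  raw <- strsplit(lines, sep, fixed = TRUE)
  if (length(unique(lengths(raw))) != 1L)
    stop("ragged rows: all rows must have the same number of fields", call. = FALSE)
  item_ids <- NULL; person_ids <- NULL
  if (header) { hd <- raw[[1L]]; raw <- raw[-1L]; item_ids <- trimws(hd) }
  M <- do.call(rbind, raw)
  if (ids) {
    person_ids <- trimws(M[, 1L]); M <- M[, -1L, drop = FALSE]
    if (header) item_ids <- item_ids[-1L]
  }
  vals <- trimws(M)
  y <- matrix(NA_integer_, nrow(vals), ncol(vals))
  for (jj in seq_len(ncol(vals))) {
    v <- vals[, jj]
    bad <- !(v %in% c("0", "1", missing))
    if (any(bad))
      stop(sprintf("invalid cell '%s' at row %d, column %d (expected 0, 1 or %s)",
                   v[which(bad)[1L]], which(bad)[1L], jj, missing), call. = FALSE)
    col <- rep(NA_integer_, length(v))
    col[v != missing] <- as.integer(v[v != missing])
    y[, jj] <- col
  }
  response_matrix(y, person_ids = person_ids, item_ids = item_ids)
}

#' Write a response matrix as delimited text
#'
#' @param y A [response_matrix()].
#' @param path Output file.
#' @inheritParams read_response_matrix
#' @export
write_response_matrix <- function(y, path, sep = ",", missing = "NA") {
  stopifnot(inherits(y, "response_matrix"))
  m <- y$y
  body <- apply(m, 1L, function(row)
    paste(ifelse(is.na(row), missing, as.character(row)), collapse = sep))
  lines <- c(paste(c("person", y$item_ids), collapse = sep),
             paste(y$person_ids, body, sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fit summary table
#'
#' Delimited table with columns parameter, mean, sd, hdi_low, hdi_high,
#' rhat, ess (the MML results table mirrors the schema with NA in the
#' HDI/R-hat columns).
#'
#' @param fit A `fit_result` or `mml_result`.
#' @param path Output file.
#' @export
write_fit_summary <- function(fit, path) {
  tab <- summary_table(fit)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Summary table of a fit in the common schema
#'
#' @param fit A `fit_result` or `mml_result`.
#' @export
summary_table <- function(fit) {
  if (inherits(fit, "fit_result")) {
    if (is.null(fit$summary)) stop("fit failed; no summary available", call. = FALSE)
    return(fit$summary[, c("parameter", "mean", "sd", "hdi_low", "hdi_high",
                           "rhat", "ess")])
  }
  stopifnot(inherits(fit, "mml_result"))
  si <- fit$slope_intercept
  I <- length(si$a)
  cl <- slope_intercept_to_classical(si)
  data.frame(
    parameter = c(sprintf("alpha[%d]", seq_len(I)), sprintf("beta[%d]", seq_len(I)),
                  sprintf("theta[%d]", seq_along(fit$theta))),
    mean = c(cl$alpha, cl$beta, fit$theta),
    sd = NA_real_, hdi_low = NA_real_, hdi_high = NA_real_, rhat = NA_real_,
    ess = NA_real_, stringsAsFactors = FALSE)
}

#' Serialize / load a generated dataset directory
#'
#' Writes `responses.csv` (delimited responses), `truth.csv` (true item
#' parameters), `theta.csv` (true abilities) and `condition.yml`
#' (condition, seed and true covariance).
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Target directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "generated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_response_matrix(dataset$responses, file.path(dir, "responses.csv"))
  utils::write.csv(data.frame(item = dataset$responses$item_ids,
                              alpha = dataset$items$alpha,
                              beta = dataset$items$beta),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(person = dataset$responses$person_ids,
                              theta = dataset$theta),
                   file.path(dir, "theta.csv"), row.names = FALSE)
  cond <- dataset$condition
  yaml::write_yaml(list(n_persons = cond$n_persons, n_items = cond$n_items,
                        tau_pair = cond$tau_pair, rho = cond$rho,
                        seed = cond$seed,
                        sigma = as.numeric(dataset$sigma)),
                   file.path(dir, "condition.yml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  responses <- read_response_matrix(file.path(dir, "responses.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  th <- utils::read.csv(file.path(dir, "theta.csv"))
  meta <- yaml::read_yaml(file.path(dir, "condition.yml"))
  cond <- generating_condition(meta$n_persons, meta$n_items,
                               unlist(meta$tau_pair), meta$rho, meta$seed)
  structure(list(responses = responses,
                 items = item_parameters(truth$alpha, truth$beta),
                 theta = th$theta,
                 sigma = matrix(unlist(meta$sigma), 2L, 2L),
                 condition = cond),
            class = "generated_dataset")
}

#' Read a model/run configuration file
#'
#' YAML key/value file; keys mirror the CLI flags (model, family, spec,
#' eta, chains, iterations, burnin, seed, ...). Values given on the command
#' line are overridden by the file.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}
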