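# The log-joint builders are checked term by term against independent
# summation oracles on toy datasets, and the compiled likelihood against the
# reference R implementation.

toy_y <- function() response_matrix(rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L)))

test_that("2PL log-likelihood matches a naive dbinom oracle, missing cells ignored", {
  set.seed(7)
  Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  alpha <- c(0.8, 1.5, 2.2); beta <- c(-0.5, 0, 1); theta <- rnorm(4)
  y <- response_matrix(Y)
  items <- item_parameters(alpha, beta)
  expect_equal(loglik_2pl(y, items, theta), oracle_loglik(Y, alpha, beta, theta),
               tolerance = 1e-10)

  # single cell: alpha=1, beta=0, theta=0, y=1 contributes log(0.5)
  y1 <- response_matrix(matrix(1L, 1, 1))
  expect_equal(loglik_2pl(y1, item_parameters(1, 0), 0), log(0.5),
               tolerance = 1e-12)

  # adding a missing cell leaves the value unchanged
  Y2 <- cbind(Y, NA_integer_)
  y2 <- response_matrix(Y2, require_complete_margins = FALSE)
  items2 <- item_parameters(c(alpha, 1), c(beta, 0))
  expect_equal(loglik_2pl(y2, items2, theta),
               loglik_2pl(y, items, theta), tolerance = 1e-12)
})

test_that("compiled likelihood agrees with the reference implementation", {
  set.seed(11)
  for (rep in 1:5) {
    N <- sample(2:40, 1); I <- sample(2:15, 1)
    Y <- matrix(rbinom(N * I, 1, 0.5), N, I)
    Y[sample(N * I, floor(N * I / 10))] <- NA_integer_
    alpha <- runif(I, 0.3, 3); beta <- rnorm(I); theta <- rnorm(N)
    y <- response_matrix(Y, require_complete_margins = FALSE)
    expect_equal(hier2pl:::.cpp_loglik_2pl(y$y, alpha, beta, theta),
                 loglik_2pl(y, item_parameters(alpha, beta), theta),
                 tolerance = 1e-10)
  }
})

test_that("non-centered hierarchical log joint equals the term-by-term oracle", {
  # moderate fixed values keep the naive oracle away from p underflowing to
  # exactly 0/1, where only the package's safe form stays accurate
  y <- toy_y()
  xt <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)
  theta <- c(-0.6, 0.1, 1.2)
  L <- corr_chol_2d(0.4)

  for (cfg in list(hyperprior_config("half_cauchy", "WI2"),
                   hyperprior_config("exponential", "WI1"),
                   hyperprior_config("inverse_gamma", "WI1"))) {
    st <- if (cfg$family == "inverse_gamma") {
      noncentered_state(xt, mu_alpha = 0.2, mu_beta = -0.3, L_Omega = L,
                        theta = theta, tau_alpha = 0.3, tau_beta = 0.8)
    } else {
      hi <- if (cfg$family == "half_cauchy") pi / 2 else 1
      noncentered_state(xt, mu_alpha = 0.2, mu_beta = -0.3, L_Omega = L,
                        theta = theta, tau_alpha_unif = 0.2 * hi,
                        tau_beta_unif = 0.4 * hi)
    }
    cl <- noncentered_to_classical(st, cfg)
    expected <- oracle_loglik(y$y, cl$items$alpha, cl$items$beta, theta) +
      sum(dnorm(theta, log = TRUE)) + sum(dnorm(xt, log = TRUE)) +
      dnorm(0.2, 0, 1, log = TRUE) + dnorm(-0.3, 0, 2, log = TRUE) +
      (2 - 2 + 2 * cfg$eta - 2) * log(L[2, 2])
    if (cfg$family == "inverse_gamma") {
      a <- cfg$params$a; b <- cfg$params$b
      ig <- function(x) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
      expected <- expected + ig(0.3) + ig(0.8)
    }
    expect_equal(log_joint_hier2pl(st, y, cfg), expected, tolerance = 1e-8,
                 label = cfg$family)
  }
})

test_that("auxiliaries outside their bounded support are rejected", {
  y <- toy_y()
  cfg <- hyperprior_config("exponential", "WI2")
  st <- noncentered_state(matrix(0, 2, 2), 0, 0, diag(2), theta = rnorm(3),
                          tau_alpha_unif = 1.2, tau_beta_unif = 0.5)
  expect_error(log_joint_hier2pl(st, y, cfg), "strictly inside")
  expect_error(log_joint_hier2pl(st, y, hyperprior_config("inverse_wishart")),
               "centered comparator")
})

test_that("inverse-Wishart density and centered log joint match closed forms", {
  # IW(3, I) at Sigma = I, p = 2: -(nu p / 2) log 2 - log Gamma_2(nu/2) - tr/2
  nu <- 3
  lg2 <- 0.5 * log(pi) + lgamma(nu / 2) + lgamma(nu / 2 - 0.5)
  expect_equal(dinvwishart_log(diag(2), nu, diag(2)),
               -nu * log(2) - lg2 - 1, tolerance = 1e-10)

  set.seed(5)
  y <- toy_y()
  params <- list(theta = rnorm(3), log_alpha = c(0.1, -0.2), beta = c(0.4, -1),
                 mu = c(0.05, -0.2),
                 Sigma = matrix(c(0.09, 0.03, 0.03, 0.8), 2, 2))
  Si <- solve(params$Sigma)
  quad <- function(v) {
    d <- v - params$mu
    -log(2 * pi) - 0.5 * log(det(params$Sigma)) - 0.5 * drop(t(d) %*% Si %*% d)
  }
  expected <- oracle_loglik(y$y, exp(params$log_alpha), params$beta, params$theta) +
    sum(dnorm(params$theta, log = TRUE)) +
    quad(c(params$log_alpha[1], params$beta[1])) +
    quad(c(params$log_alpha[2], params$beta[2])) +
    dnorm(params$mu[1], 0, 1, log = TRUE) + dnorm(params$mu[2], 0, 2, log = TRUE) +
    dinvwishart_log(params$Sigma, 3, diag(2))
  expect_equal(log_joint_iw2pl(params, y), expected, tolerance = 1e-8)
  bad <- params; bad$Sigma <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(log_joint_iw2pl(bad, y), "positive definite")
})

test_that("nonhierarchical log joint uses lognormal and N(0,2) priors", {
  y <- toy_y()
  set.seed(9)
  params <- list(theta = rnorm(3), alpha = c(1, 1.7), beta = c(0, -0.8))
  expected <- oracle_loglik(y$y, params$alpha, params$beta, params$theta) +
    sum(dnorm(params$theta, log = TRUE)) +
    # lognormal(0,1) at alpha = 1: density 1/sqrt(2 pi)
    (-log(sqrt(2 * pi))) + dlnorm(1.7, 0, 1, log = TRUE) +
    # normal(0, sd 2) at beta = 0: density 1/(2 sqrt(2 pi))
    (-log(2 * sqrt(2 * pi))) + dnorm(-0.8, 0, 2, log = TRUE)
  expect_equal(log_joint_simple2pl(params, y), expected, tolerance = 1e-10)
  expect_error(log_joint_simple2pl(list(theta = 0, alpha = -1, beta = 0),
                                   response_matrix(matrix(1L, 1, 1))),
               "positive")
  # variance reading shifts only the beta and mu terms
  v <- log_joint_simple2pl(params, y, scale_reading = "variance")
  expected_v <- expected - dnorm(-0.8, 0, 2, log = TRUE) + log(2 * sqrt(2 * pi)) +
    dnorm(0, 0, sqrt(2), log = TRUE) + dnorm(-0.8, 0, sqrt(2), log = TRUE)
  expect_equal(v, expected_v, tolerance = 1e-10)
})
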