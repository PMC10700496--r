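test_that("logistic response function matches direct evaluation and limits", {
  expect_identical(irt_logit(0), 0.5)
  expect_equal(irt_logit(2), 0.8807970779778823, tolerance = 1e-12)
  expect_equal(irt_logit(800), 1)     # overflow-safe at extreme logits
  expect_equal(irt_logit(-800), 0)
  expect_error(irt_logit(Inf), "finite")
  expect_error(irt_logit(NA_real_), "finite")
})

test_that("2PL response probability is 0.5 at theta = beta and monotone", {
  for (a in c(0.3, 1, 2.7)) expect_equal(response_probability(1.2, a, 1.2), 0.5)
  expect_equal(response_probability(1, 2, 0), 0.8807970779778823,
               tolerance = 1e-12)
  th <- seq(-3, 3, by = 0.25)
  p <- response_probability(th, 1.4, 0.5)
  expect_true(all(diff(p) > 0))
  # monotone decreasing in beta
  p_b <- response_probability(0.5, 1.4, th)
  expect_true(all(diff(p_b) < 0))
  expect_error(response_probability(0, -1, 0), "positive")
  expect_error(response_probability(0, 0, 0), "positive")
})

test_that("tangent transform pushes Uniform(0, pi/2) to the half-Cauchy", {
  expect_equal(half_cauchy_from_uniform(pi / 4, 2.5), 2.5, tolerance = 1e-12)
  u <- seq(0.05, 1.5, by = 0.05)
  expect_true(all(diff(half_cauchy_from_uniform(u, 2.5)) > 0))
  expect_lt(half_cauchy_from_uniform(1e-10, 2.5), 1e-9)
  expect_error(half_cauchy_from_uniform(0, 2.5), "strictly inside")
  expect_error(half_cauchy_from_uniform(pi / 2, 2.5), "strictly inside")

  set.seed(101)
  draws <- half_cauchy_from_uniform(runif(1e5, 1e-12, pi / 2 - 1e-12), 2.5)
  d <- ks_distance(draws, function(x) 2 * pcauchy(x, 0, 2.5) - 1)
  expect_lt(d, 0.01)
})

test_that("log transform pushes Uniform(0, 1) to the Exponential", {
  expect_equal(exponential_from_uniform(exp(-1), 2.5), 2.5, tolerance = 1e-12)
  expect_lt(exponential_from_uniform(1 - 1e-12, 2.5), 1e-8)
  expect_error(exponential_from_uniform(1, 2.5), "strictly inside")
  expect_error(exponential_from_uniform(-0.1, 2.5), "strictly inside")

  set.seed(202)
  draws <- exponential_from_uniform(runif(1e6), 2.5)
  expect_lt(abs(mean(draws) - 2.5), 0.01)
  d <- ks_distance(draws[1:1e5], function(x) pexp(x, rate = 1 / 2.5))
  expect_lt(d, 0.01)
})

test_that("LKJ Cholesky log-density follows the printed product formula", {
  expect_identical(lkj_chol_log_density(diag(2), 2), 0)
  expect_identical(lkj_chol_log_density(diag(2), 17.3), 0)
  L <- rbind(c(1, 0), c(0.6, 0.8))
  expect_equal(lkj_chol_log_density(L, 2), 2 * log(0.8), tolerance = 1e-12)
  # eta = 2 favors small correlations: maximal at the identity factor
  vals <- sapply(seq(-0.9, 0.9, by = 0.1),
                 function(r) lkj_chol_log_density(corr_chol_2d(r), 2))
  expect_equal(which.max(vals), which(seq(-0.9, 0.9, by = 0.1) == 0))
  expect_error(lkj_chol_log_density(rbind(c(1, 0), c(1.2, -0.3)), 2), "positive")
})

test_that("non-centered to classical reconstruction matches hand evaluation", {
  I <- 4L
  zero <- matrix(0, 2, I)
  cfg <- hyperprior_config("half_cauchy", "WI2")
  st <- noncentered_state(zero, mu_alpha = 0, mu_beta = 0, L_Omega = diag(2),
                          tau_alpha_unif = pi / 4, tau_beta_unif = pi / 4)
  cl <- noncentered_to_classical(st, cfg)
  expect_equal(cl$items$alpha, rep(1, I))
  expect_equal(cl$items$beta, rep(0, I))
  expect_equal(cl$hyper$tau_alpha, 2.5)

  st2 <- noncentered_state(zero, mu_alpha = 0.5, mu_beta = -1, L_Omega = diag(2),
                           tau_alpha_unif = pi / 4, tau_beta_unif = pi / 4)
  cl2 <- noncentered_to_classical(st2, cfg)
  expect_equal(cl2$items$alpha, rep(exp(0.5), I), tolerance = 1e-12)
  expect_equal(cl2$items$beta, rep(-1, I))

  # identity factor, tau_alpha = 0.2, single unit z-score
  xt <- zero; xt[1, 1] <- 1
  cfg_ig <- hyperprior_config("inverse_gamma", "WI1")
  st3 <- noncentered_state(xt, mu_alpha = 0, mu_beta = 0, L_Omega = diag(2),
                           tau_alpha = 0.2, tau_beta = 0.9)
  cl3 <- noncentered_to_classical(st3, cfg_ig)
  expect_equal(cl3$items$alpha[1], exp(0.2), tolerance = 1e-12)
  expect_equal(cl3$items$alpha[2], 1)
})

test_that("classical <-> non-centered round trip is exact for every family", {
  set.seed(33)
  for (cfg in list(hyperprior_config("half_cauchy", "WI2"),
                   hyperprior_config("exponential", "NI1"),
                   hyperprior_config("inverse_gamma", "WI1"))) {
    for (rep in 1:5) {
      I <- sample(3:12, 1)
      hyper <- hyper_parameters(mu_alpha = rnorm(1, 0, 0.5),
                                mu_beta = rnorm(1),
                                tau_alpha = runif(1, 0.05, 1),
                                tau_beta = runif(1, 0.2, 1.5),
                                L_Omega = corr_chol_2d(runif(1, -0.8, 0.8)))
      items <- item_parameters(alpha = exp(rnorm(I, hyper$mu_alpha, 0.4)),
                               beta = rnorm(I, hyper$mu_beta, 1))
      st <- classical_to_noncentered(items, hyper, cfg)
      back <- noncentered_to_classical(st, cfg)
      expect_equal(back$items$alpha, items$alpha, tolerance = 1e-10)
      expect_equal(back$items$beta, items$beta, tolerance = 1e-10)
      expect_equal(back$hyper$tau_alpha, hyper$tau_alpha, tolerance = 1e-10)
      expect_equal(back$hyper$tau_beta, hyper$tau_beta, tolerance = 1e-10)
    }
  }
})

test_that("hyperprior catalogue resolves the twelve specifications", {
  tab <- hyperprior_table()
  expect_identical(nrow(tab), 12L)
  expect_equal(hyperprior_config("half_cauchy", "NI2")$params$scale, 25)
  expect_equal(hyperprior_config("exponential", "WI2")$params$inverse_scale, 0.4)
  cfg <- hyperprior_config("inverse_gamma", "NI2")
  expect_equal(cfg$params$a, 0.001)
  expect_equal(cfg$params$b, 0.001)
  expect_error(hyperprior_config("half_cauchy", "XX"), "unknown specification")
  expect_error(hyperprior_config("exponential"), "explicit hyperparameters")
})
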