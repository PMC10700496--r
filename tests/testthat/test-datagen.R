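test_that("truncated draws always fall inside the box", {
  set.seed(1)
  box <- truncation_box()
  Z <- draw_truncated_bvn(2000, box, diag(c(0.25, 0.9)^2))
  expect_true(all(Z[, 1] > 0.65 & Z[, 1] < 4.0))
  expect_true(all(Z[, 2] > -4.5 & Z[, 2] < 4.5))
})

test_that("without truncation the draw reproduces the target covariance", {
  set.seed(2)
  wide <- truncation_box(grand_mean = c(1, 0), lower = c(-1e6, -1e6),
                         upper = c(1e6, 1e6))
  Sigma <- matrix(c(0.0625, 0.3 * 0.25 * 0.9, 0.3 * 0.25 * 0.9, 0.81), 2, 2)
  Z <- draw_truncated_bvn(1e5, wide, Sigma)
  # Monte-Carlo tolerance: about 3 standard errors of a variance estimate
  expect_equal(cov(Z)[1, 1], Sigma[1, 1], tolerance = 3 * sqrt(2 / 1e5))
  expect_equal(cov(Z)[2, 2], Sigma[2, 2], tolerance = 3 * sqrt(2 / 1e5))
  expect_equal(cor(Z)[1, 2], 0.3, tolerance = 3 / sqrt(1e5))
  expect_equal(colMeans(Z), c(1, 0), tolerance = 0.02)
})

test_that("a narrow box shrinks the variance below the nominal one", {
  set.seed(3)
  tight <- truncation_box(grand_mean = c(1, 0), lower = c(0.9, -0.1),
                          upper = c(1.1, 0.1))
  Z <- draw_truncated_bvn(5000, tight, diag(c(1, 1)))
  expect_lt(var(Z[, 1]), 0.1)
  expect_lt(var(Z[, 2]), 0.1)
})

test_that("exact covariance rescaling hits the target to numerical precision", {
  set.seed(4)
  Z <- matrix(rnorm(100), 50, 2) %*% rbind(c(1, 0.5), c(0, 2))
  target <- matrix(c(0.0625, 0, 0, 0.81), 2, 2)
  X <- exact_covariance_rescale(Z, target)
  expect_equal(sd(X[, 1]), 0.25, tolerance = 1e-10)
  expect_equal(sd(X[, 2]), 0.90, tolerance = 1e-10)
  expect_lt(abs(cov(X)[1, 2]), 1e-10)

  t2 <- matrix(c(0.0625, 0.3 * 0.25 * 0.9, 0.3 * 0.25 * 0.9, 0.81), 2, 2)
  X2 <- exact_covariance_rescale(Z, t2)
  expect_equal(cor(X2)[1, 2], 0.3, tolerance = 1e-10)

  # idempotent on the covariance: rescaling a conforming sample keeps it
  X3 <- exact_covariance_rescale(X2, t2)
  expect_equal(cov(X3), t2, tolerance = 1e-10)

  expect_error(exact_covariance_rescale(cbind(1:5, 2 * (1:5)), target),
               "singular")
  # the n-denominator variant is exact under its own convention
  Xn <- exact_covariance_rescale(Z, target, denominator = "n")
  expect_equal(sum(Xn[, 1]^2) / 50, 0.0625, tolerance = 1e-10)
})

test_that("truncated-normal marginal means match closed forms", {
  # no truncation: means are the grand means
  wide <- truncation_box(c(1, 0), c(-1e5, -1e5), c(1e5, 1e5))
  expect_equal(truncated_bvn_means(wide, diag(2)), c(1, 0), tolerance = 1e-10)

  # independent components: means follow the univariate truncated formula
  box <- truncation_box()
  S <- diag(c(0.25, 0.9)^2)
  m <- truncated_bvn_means(box, S)
  tmean <- function(mu, s, a, b) {
    za <- (a - mu) / s; zb <- (b - mu) / s
    mu + s * (dnorm(za) - dnorm(zb)) / (pnorm(zb) - pnorm(za))
  }
  expect_equal(m[1], tmean(1, 0.25, 0.65, 4.0), tolerance = 1e-8)
  expect_equal(m[2], tmean(0, 0.9, -4.5, 4.5), tolerance = 1e-8)

  # half-normal limit: N(0,1) truncated at zero has mean sqrt(2/pi)
  half <- truncation_box(c(1e-9, 0), c(0, -100), c(100, 100))
  expect_equal(truncated_bvn_means(half, diag(2))[1], sqrt(2 / pi),
               tolerance = 1e-6)
})

test_that("recentring is a pure per-column shift onto the truncated means", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  box <- truncation_box()
  S <- condition_sigma(generating_condition(10, 30, c(0.25, 0.9), 0.3))
  Y <- recentre_to_truncated_means(X, box, S)
  expect_equal(colMeans(Y), truncated_bvn_means(box, S), tolerance = 1e-12)
  shift <- Y - X
  expect_equal(max(abs(sweep(shift, 2, colMeans(shift)))), 0, tolerance = 1e-12)
})

test_that("generated item parameters reproduce the target moments exactly", {
  for (seed in c(1, 7, 1234)) {
    set.seed(seed)
    cond <- generating_condition(100, 50, c(0.25, 0.90), 0.3, seed = seed)
    gen <- generate_item_parameters(cond)
    expect_equal(sd(gen$items$alpha), 0.25, tolerance = 1e-10)
    expect_equal(sd(gen$items$beta), 0.90, tolerance = 1e-10)
    expect_equal(cor(gen$items$alpha, gen$items$beta), 0.3, tolerance = 1e-10)
    expect_true(all(gen$items$alpha > 0.5 & gen$items$alpha < 3.5))
    expect_true(all(gen$items$beta > -4 & gen$items$beta < 4))
  }
  # uncorrelated condition
  set.seed(8)
  gen0 <- generate_item_parameters(generating_condition(50, 25, c(0.10, 0.40), 0))
  expect_lt(abs(cor(gen0$items$alpha, gen0$items$beta)), 1e-10)
  expect_error(generating_condition(50, 2, c(0.25, 0.9), 0.3), "n_items")
})

test_that("abilities are standard normal and responses Bernoulli-consistent", {
  set.seed(9)
  th <- generate_abilities(1e5)
  expect_lt(abs(mean(th)), 3 / sqrt(1e5))
  expect_lt(abs(sd(th) - 1), 3 / sqrt(2 * 1e5))

  set.seed(10); a <- generate_abilities(50)
  set.seed(10); b <- generate_abilities(50)
  expect_identical(a, b)

  # cellwise response frequency matches the model probability
  items <- item_parameters(c(1.8, 0.7), c(-0.4, 0.6))
  theta0 <- 0.3
  set.seed(11)
  y <- generate_responses(rep(theta0, 1e4), items)
  p <- response_probability(theta0, items$alpha, items$beta)
  freq <- colMeans(y$y)
  se <- sqrt(p * (1 - p) / 1e4)
  expect_true(all(abs(freq - p) < 3 * se))

  # theta = beta everywhere: proportion correct about one half
  it2 <- item_parameters(rep(2, 5), rep(0.7, 5))
  set.seed(12)
  y2 <- generate_responses(rep(0.7, 2000), it2)
  expect_equal(mean(y2$y), 0.5, tolerance = 0.02)

  # a very discriminating item is answered correctly when theta > beta
  it3 <- item_parameters(500, 0)
  set.seed(13)
  y3 <- generate_responses(rep(1, 200), it3)
  expect_true(all(y3$y == 1L))
})

test_that("datasets are deterministic per seed and fresh across replications", {
  cond <- generating_condition(40, 10, c(0.25, 0.9), 0.3, seed = 77)
  d1 <- generate_dataset(cond)
  d2 <- generate_dataset(cond)
  expect_identical(d1$responses$y, d2$responses$y)
  expect_identical(d1$items$alpha, d2$items$alpha)
  cond2 <- cond; cond2$seed <- 78L
  d3 <- generate_dataset(cond2)
  expect_false(identical(d1$items$alpha, d3$items$alpha))
  expect_false(identical(d1$responses$y, d3$responses$y))
})
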