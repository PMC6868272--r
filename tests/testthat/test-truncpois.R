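test_that("truncated Poisson pmf normalises and matches brute force", {
  # sums to one for a spread of rates
  for (lam in c(1e-6, 0.3, 1, 3, 25))
    expect_equal(sum(dtruncpois(0:3, lam)), 1, tolerance = 1e-12)
  # small-rate limit piles all mass on zero
  expect_gt(dtruncpois(0, 1e-9), 1 - 1e-8)
  # lambda = 1: probabilities proportional to 1/k!, normalised directly
  w <- 1 / factorial(0:3)
  expect_equal(dtruncpois(0:3, 1), w / sum(w), tolerance = 1e-12)
  expect_error(dtruncpois(4, 1), "0..K")
  expect_error(dtruncpois(1, -2), "positive")
  # expected score bounded by K and increasing in lambda
  lam <- seq(0.05, 30, length.out = 40)
  m <- truncpois_mean(lam)
  expect_true(all(diff(m) > 0))
  expect_true(all(m < 3))
})

test_that("MLE matches an untruncated Poisson GLM when truncation never binds", {
  set.seed(21)
  n <- 3000
  x <- stats::rnorm(n)
  lam <- exp(-3 + 0.3 * x)           # so small that P(Y > 3) < 1e-6
  y <- stats::rpois(n, lam)
  stopifnot(all(y <= 3))
  dat <- data.frame(y = y, x = x)
  fit <- fit_trunc_poisson(y ~ x, dat)
  oracle <- stats::glm(y ~ x, poisson(), dat,
                       control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(stats::coef(oracle)),
               tolerance = 1e-4)
})

test_that("parameters are recovered from data simulated under the model", {
  set.seed(31)
  n <- 5000
  beta <- c(-0.2, -0.35, 0.2)
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  lam <- exp(beta[1] + beta[2] * x1 + beta[3] * x2)
  # sample from the truncated pmf by inversion
  P <- t(vapply(lam, function(l) cumsum(dtruncpois(0:3, l)), numeric(4)))
  y <- max.col(P >= stats::runif(n), ties.method = "first") - 1L
  dat <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- fit_trunc_poisson(y ~ x1 + x2, dat, method = "bayes",
                           chains = 2, iter = 800, burn = 300, seed = 5)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
  # posterior intervals behave for a null covariate
  dat$z <- stats::rnorm(n)
  fit0 <- fit_trunc_poisson(y ~ x1 + z, dat, method = "bayes",
                            chains = 2, iter = 800, burn = 300, seed = 6)
  qs <- stats::quantile(fit0$draws[, "z"], c(0.025, 0.975))
  expect_lt(qs[1], 0)
  expect_gt(qs[2], 0)
})

test_that("prediction curves are flat/monotone as the coefficients dictate", {
  set.seed(41)
  n <- 800
  dat <- data.frame(y = sample(0:3, n, TRUE, prob = c(.5, .3, .15, .05)),
                    g = stats::runif(n, 0, 8))
  flat <- fit_trunc_poisson(y ~ 1, dat)
  grid <- data.frame(g = seq(0, 8, 1))
  pf <- predict(flat, grid)$fit
  expect_equal(diff(range(pf)), 0)

  # negative generation coefficient -> strictly decreasing expected score
  lam <- exp(0.2 - 0.25 * dat$g)
  P <- t(vapply(lam, function(l) cumsum(dtruncpois(0:3, l)), numeric(4)))
  dat$y2 <- max.col(P >= stats::runif(n), ties.method = "first") - 1L
  dec <- fit_trunc_poisson(y2 ~ g, dat)
  expect_lt(coef(dec)[["g"]], 0)
  curve <- predict_score_curve(dec, grid)
  expect_true(all(diff(curve$fit) < 0))
  red <- score_reduction(dec, grid[1, , drop = FALSE], grid[9, , drop = FALSE])
  expect_equal(red$reduction_pct,
               100 * (1 - curve$fit[9] / curve$fit[1]), tolerance = 1e-10)
})

test_that("mass-vs-generations slope is recovered and scales arithmetically", {
  set.seed(51)
  n <- 2000
  d <- data.frame(mean_ancestor_score = stats::runif(n, 0, 8),
                  age_days = stats::rnorm(n, 520, 120),
                  sex = sample(c("female", "male"), n, TRUE))
  d$residual_mass <- -0.033 * d$mean_ancestor_score + stats::rnorm(n, 0, 0.5)
  fit <- fit_mass_vs_generations(d)
  expect_lt(abs(fit$slope_kg_per_gen - (-0.033)), 0.01)
  expect_equal(fit$change_after_horizon, 8 * fit$slope_kg_per_gen)

  set.seed(60)
  d$residual_mass <- stats::rnorm(n, 0, 0.5)
  fit0 <- fit_mass_vs_generations(d)
  expect_lt(fit0$slope_ci[1], 0)
  expect_gt(fit0$slope_ci[2], 0)
})
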