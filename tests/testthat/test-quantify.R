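test_that("z-transform standardises to mean 0 and unit sample sd", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  v <- with_seed(1, rnorm(40, 5, 3))
  z <- z_transform(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(z_transform(5), "at least 2")
  expect_error(z_transform(c(2, 2, 2)), "constant")
})

test_that("OLS recovers exact fits and matches the normal equations", {
  x <- c(0, 1, 2, 3, 4)
  fit <- ols_fit(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  # hand dataset against the closed-form normal-equation solution
  xh <- c(1.2, 2.5, 3.1, 4.8, 6.0)
  yh <- c(2.0, 2.9, 4.2, 4.1, 6.3)
  X <- cbind(1, xh)
  beta <- solve(t(X) %*% X, t(X) %*% yh)
  fh <- ols_fit(xh, yh)
  expect_equal(fh$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fh$slope, beta[2], tolerance = 1e-10)
  expect_equal(fh$r_squared,
               1 - sum((yh - X %*% beta)^2) / sum((yh - mean(yh))^2),
               tolerance = 1e-10)

  # independent y: R^2 near zero
  with_seed(5, {
    xi <- rnorm(1000); yi <- rnorm(1000)
    expect_lt(ols_fit(xi, yi)$r_squared, 0.01)
  })
})

test_that("GLS with delta fixed at zero reproduces OLS exactly", {
  with_seed(9, {
    x <- rnorm(60); y <- 1 + 0.5 * x + rnorm(60, sd = 0.4)
  })
  o <- ols_fit(x, y)
  g <- gls_varexp_fit(x, y, delta = 0)
  expect_equal(g$intercept, o$intercept, tolerance = 1e-8)
  expect_equal(g$slope, o$slope, tolerance = 1e-8)
  expect_equal(g$sigma, o$sigma, tolerance = 1e-8)
  expect_equal(g$log_likelihood, o$log_likelihood, tolerance = 1e-8)
})

test_that("homoscedastic data give near-zero delta and the OLS slope", {
  with_seed(12, {
    x <- rnorm(500); y <- 0.3 + 0.8 * x + rnorm(500, sd = 0.5)
  })
  g <- gls_varexp_fit(x, y)
  expect_lt(abs(g$delta), 0.05)
  expect_equal(g$slope, ols_fit(x, y)$slope, tolerance = 1e-3)
  # optimisation sanity: profile optimum at least as likely as delta = 0
  expect_gte(g$log_likelihood, gls_varexp_fit(x, y, delta = 0)$log_likelihood)
})

test_that("varExp profile likelihood matches a dense grid search", {
  x <- c(-1.5, -0.8, -0.2, 0.1, 0.6, 1.1, 1.7, 2.3)
  y <- c(-0.9, -0.5, -0.3, 0.2, 0.1, 1.4, 0.4, 2.9)
  deltas <- seq(-3, 3, by = 1e-4)
  n <- length(x)
  W <- exp(-2 * outer(deltas, x))
  sw <- rowSums(W)
  xw <- (W %*% x) / sw
  yw <- (W %*% y) / sw
  sxx <- rowSums(W * (outer(deltas, x, function(d, xx) xx) - c(xw))^2)
  sxy <- rowSums(W * (outer(rep(1, length(deltas)), x) - c(xw)) *
                   (outer(rep(1, length(deltas)), y) - c(yw)))
  slope <- sxy / sxx
  intercept <- c(yw) - slope * c(xw)
  res2 <- (outer(rep(1, length(deltas)), y) - intercept -
             slope * outer(rep(1, length(deltas)), x))^2
  sigma2 <- rowSums(W * res2) / n
  ll <- -n / 2 * log(2 * pi * sigma2) - deltas * sum(x) - n / 2
  best <- which.max(ll)
  fit <- gls_varexp_fit(x, y)
  expect_equal(fit$delta, deltas[best], tolerance = 1e-3)
  expect_equal(fit$slope, slope[best], tolerance = 1e-3)
  expect_equal(fit$intercept, intercept[best], tolerance = 1e-3)
  expect_equal(fit$log_likelihood, ll[best], tolerance = 1e-6)
})

test_that("varExp fit agrees with the nlme reference implementation", {
  skip_if_not_installed("nlme")
  with_seed(31, {
    x <- rnorm(200)
    y <- 0.1 + 0.6 * x + rnorm(200, sd = 0.3 * exp(0.8 * x))
  })
  fit <- gls_varexp_fit(x, y)
  ref <- nlme::gls(y ~ x, weights = nlme::varExp(form = ~x), method = "ML")
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit$delta, unname(coef(ref$modelStruct$varStruct)),
               tolerance = 1e-3)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
})

test_that("read frequencies convert to biomasses and counts conservatively", {
  one <- biomass_to_counts(c(a = 1), 10, c(a = 2))
  expect_equal(one$estimated_count, 5)
  two <- biomass_to_counts(c(a = 0.75, b = 0.25), 8, c(a = 2, b = 1))
  expect_equal(two$estimated_count, c(3, 2))
  expect_equal(sum(two$estimated_biomass), 8, tolerance = 1e-12)
  expect_error(biomass_to_counts(c(a = 0.4), 8, c(a = 2)), "sum to 1")
})
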