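test_that("joint posterior covariance matches the hand-derived Hessian inverse", {
  # log-normal two-county toy: theta = (beta, u_1, u_2), flat prior on beta,
  # N(0, s^2) on county effects, known sampling variances v
  y <- c(1.2, 0.8); v <- c(0.04, 0.09); s <- 0.3
  fit <- toy_lognormal_fit(y = y, v = v, beta = 1.0, sigma_county = s)
  jp <- eb_condition(fit)
  H <- rbind(c(1 / v[1] + 1 / v[2], 1 / v[1], 1 / v[2]),
             c(1 / v[1], 1 / v[1] + 1 / s^2, 0),
             c(1 / v[2], 0, 1 / v[2] + 1 / s^2))
  expect_equal(jp$covariance, solve(H), tolerance = 1e-10,
               ignore_attr = TRUE)
  # Gaussian case: the mode solves the normal equations H theta = X'Wy
  expect_equal(as.vector(H %*% jp$mode),
               c(sum(y / v), y[1] / v[1], y[2] / v[2]), tolerance = 1e-8)
  expect_equal(max(abs(jp$covariance - t(jp$covariance))), 0,
               tolerance = 1e-10)
})

test_that("shrinkage weakens as county population grows", {
  # counties with the same observed prevalence but growing denominators:
  # the EB estimate moves monotonically toward the raw estimate
  out <- simulate_universe(J = 4, counties_per_state = 10, seed = 51)
  u <- out$universe
  births <- c(100, 400, 1600, 6400, 25600, 102400, 409600, 1638400)
  idx <- seq_along(births)
  u$low_birth_weight$births[idx] <- births
  u$low_birth_weight$events[idx] <- as.integer(round(0.13 * births))
  u$low_birth_weight$suppressed[idx] <- FALSE
  f <- fit_binomial(u, "low_birth_weight", "model1")
  jp <- eb_condition(f, u)
  eta <- as.vector(jp$mode[jp$index$beta]) +
    jp$mode[jp$index$state][jp$county_state[idx]] +
    jp$mode[jp$index$county][idx]
  eb_p <- plogis(eta)
  gap <- abs(eb_p - 0.13)
  expect_true(all(diff(gap) < 1e-6))
  # weak-shrinkage limit: the largest county reproduces its raw value
  expect_equal(eb_p[length(idx)], 0.13, tolerance = 0.01)
})

test_that("counties without data are imputed from the prior", {
  out <- simulate_universe(J = 5, counties_per_state = 8, seed = 61)
  u <- out$universe
  # censor county 3 completely for the survey measure
  u$fair_poor_health$censored[3] <- TRUE
  u$fair_poor_health[3, c("prevalence", "ci_low", "ci_high")] <- NA_real_
  f <- fit_binomial(u, "fair_poor_health", "model1")
  jp <- eb_condition(f, u)
  k <- jp$index$county[3]
  expect_equal(jp$mode[k], 0, tolerance = 1e-8)
  expect_equal(jp$covariance[k, k], f$sigma_county_hat^2, tolerance = 1e-8)
  # its county effect is independent of the data-bearing blocks
  expect_equal(max(abs(jp$covariance[k, -k])), 0, tolerance = 1e-10)

  # posterior samples spread = full prior + state/intercept uncertainty,
  # never a point value: compare to the exact Gaussian forecast variance
  smp <- draw_samples(jp, S = 4000, seed = 2)
  a <- numeric(length(jp$mode))
  a[jp$index$beta[1]] <- 1
  a[jp$index$state[jp$county_state[3]]] <- 1
  a[k] <- 1
  var_exact <- as.numeric(t(a) %*% jp$covariance %*% a)
  eta_samp <- qlogis(smp$values[, 3])
  expect_gte(var_exact, f$sigma_county_hat^2)
  expect_equal(var(eta_samp), var_exact, tolerance = 0.1)
})

test_that("posterior draws are seed-reproducible and respect the link scale", {
  fx <- fixture_fit_universe()
  f <- fx$fits$low_birth_weight
  jp <- eb_condition(f, fx$universe)
  s1 <- draw_samples(jp, S = 200, seed = 7)
  s2 <- draw_samples(jp, S = 200, seed = 7)
  expect_identical(s1$values, s2$values)
  s3 <- draw_samples(jp, S = 200, seed = 8)
  expect_false(identical(s1$values, s3$values))
  expect_true(all(s1$values > 0 & s1$values < 1))
  expect_error(draw_samples(jp, S = 50, seed = 1), "at least 100")
})

test_that("a zero covariance collapses every draw to the mode", {
  fit <- toy_lognormal_fit()
  jp <- eb_condition(fit)
  jp$covariance[] <- 0
  smp <- draw_samples(jp, S = 150, seed = 3)
  expect_equal(max(apply(smp$values, 2, sd)), 0)
  eta <- jp$mode[1] + jp$mode[2:3]
  expect_equal(smp$values[1, ], exp(eta), ignore_attr = TRUE)
  # a genuinely indefinite matrix is refused
  jp$covariance <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  expect_error(draw_samples(jp, S = 150, seed = 3), "positive semidefinite")
})

test_that("sample means concentrate on the joint mode", {
  fit <- toy_poisson_fit()
  jp <- eb_condition(fit)
  smp <- draw_samples(jp, S = 1000, seed = 12)
  # county 1 linear predictor: MC mean within 3 standard errors of the mode
  a <- c(1, 1, 0, 1, 0, 0, 0, 0, 0)  # beta + state1 + county1
  mu <- sum(a * jp$mode)
  sdv <- sqrt(as.numeric(t(a) %*% jp$covariance %*% a))
  eta1 <- log(smp$values[, 1])
  expect_lt(abs(mean(eta1) - mu), 3 * sdv / sqrt(1000))
})

test_that("an unconverged fit cannot be conditioned", {
  fit <- toy_lognormal_fit()
  fit$converged <- FALSE
  expect_error(eb_condition(fit), "converge")
})
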