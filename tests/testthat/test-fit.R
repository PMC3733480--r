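test_that("zero-heterogeneity universes give near-zero variance components", {
  prm <- sim_params(measures = list(
    premature_mortality = list(sigma_state = 0, sigma_county = 0),
    low_birth_weight = list(sigma_state = 0, sigma_county = 0)))
  out <- simulate_universe(J = 6, counties_per_state = 15, params = prm,
                           seed = 14)
  fp <- fit_poisson(out$universe, "model1")
  expect_true(fp$converged)
  expect_lte(fp$sigma_state_hat, 0.02)
  expect_lte(fp$sigma_county_hat, 0.02)
  fb <- fit_binomial(out$universe, "low_birth_weight", "model1")
  expect_lte(fb$sigma_state_hat, 0.02)
  expect_lte(fb$sigma_county_hat, 0.02)
})

test_that("a single-state universe is rejected", {
  out <- simulate_universe(J = 2, counties_per_state = 4, seed = 2)
  u <- out$universe
  for (nm in setdiff(names(u), "measures"))
    u[[nm]] <- dplyr::filter(u[[nm]], state_index == 1)
  u$geography <- countyrank:::canonical_geography(u$geography)
  class(u) <- "county_universe"
  expect_error(fit_poisson(u, "model1"), "single state|two states")
})

test_that("binomial fit at the symmetric point recovers a zero intercept", {
  out <- simulate_universe(J = 4, counties_per_state = 10, seed = 9)
  u <- out$universe
  n <- 5e5L
  u$fair_poor_health <- u$fair_poor_health %>%
    dplyr::mutate(prevalence = 0.5, n_respondents = n,
                  ci_low = 0.5 - 1.959964 * sqrt(0.25 / n),
                  ci_high = 0.5 + 1.959964 * sqrt(0.25 / n),
                  censored = FALSE)
  f <- fit_binomial(u, "fair_poor_health", "model1")
  expect_equal(f$beta$estimate[1], 0, tolerance = 1e-3)
  expect_lte(f$sigma_county_hat, 0.01)
})

test_that("censored counties are excluded from the likelihood but kept in the universe", {
  fx <- fixture_fit_universe()
  u <- fx$universe
  n_cens <- sum(u$fair_poor_health$censored)
  expect_gt(n_cens, 0)
  f <- fx$fits$fair_poor_health
  expect_lte(f$n_obs, nrow(u$fair_poor_health) - n_cens)
  expect_identical(f$N, nrow(u$geography))
})

test_that("log-normal weights scale as the inverse squared CI width", {
  fx <- fixture_fit_universe()
  u <- fx$universe
  f1 <- fit_lognormal(u, "poor_physical_days", "model1")
  u2 <- u
  obs <- !u2$poor_physical_days$censored
  mid <- u2$poor_physical_days$mean_days
  half <- (u2$poor_physical_days$ci_high - u2$poor_physical_days$ci_low) / 4
  u2$poor_physical_days$ci_low[obs] <- (mid - half)[obs]
  u2$poor_physical_days$ci_high[obs] <- (mid + half)[obs]
  f2 <- fit_lognormal(u2, "poor_physical_days", "model1")
  # halving every CI width quarters every sampling variance
  expect_equal(f2$eb_data$v, f1$eb_data$v / 4, tolerance = 1e-10)
})

test_that("identical reported means give near-zero variance components", {
  out <- simulate_universe(J = 4, counties_per_state = 8, seed = 33)
  u <- out$universe
  u$poor_mental_days <- u$poor_mental_days %>%
    dplyr::mutate(mean_days = 3.5, ci_low = 3.2, ci_high = 3.8,
                  censored = FALSE)
  f <- fit_lognormal(u, "poor_mental_days", "model1")
  expect_true(f$converged)
  expect_lte(f$sigma_state_hat, 1e-3)
  expect_lte(f$sigma_county_hat, 1e-3)
  expect_equal(f$beta$estimate[1], log(3.5), tolerance = 1e-6)
})

test_that("nonpositive derived sampling variance is an error naming the county", {
  out <- simulate_universe(J = 2, counties_per_state = 3, seed = 4)
  u <- out$universe
  u$poor_physical_days$ci_low[2] <- u$poor_physical_days$mean_days[2]
  u$poor_physical_days$ci_high[2] <- u$poor_physical_days$mean_days[2]
  expect_error(fit_lognormal(u, "poor_physical_days", "model1"),
               "nonpositive.*j=")
})

test_that("tidy and glance expose the fit in broom shape", {
  fx <- fixture_fit_universe()
  f <- fx$fits$premature_mortality
  td <- generics::tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 9L)  # nine age-group intercepts under model 1
  gl <- generics::glance(f)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("sigma_state_hat", "sigma_county_hat", "loglik",
                    "converged") %in% names(gl)))
  expect_true(gl$converged)
  expect_true(is.finite(gl$loglik))
})
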