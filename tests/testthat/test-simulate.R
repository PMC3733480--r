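test_that("a fixed seed reproduces the universe exactly", {
  a <- simulate_universe(J = 3, counties_per_state = c(3, 6), seed = 99)
  b <- simulate_universe(J = 3, counties_per_state = c(3, 6), seed = 99)
  expect_identical(a$universe, b$universe)
  expect_identical(a$truth$true_composite, b$truth$true_composite)
  c <- simulate_universe(J = 3, counties_per_state = c(3, 6), seed = 100)
  expect_false(identical(a$universe$geography$population,
                         c$universe$geography$population))
})

test_that("degenerate variances give every county the baseline rate", {
  prm <- sim_params(
    measures = list(fair_poor_health = list(sigma_state = 0,
                                            sigma_county = 0)))
  out <- simulate_universe(J = 3, counties_per_state = 5, params = prm,
                           seed = 2)
  tv <- dplyr::filter(out$truth$true_values, measure == "fair_poor_health")
  expect_equal(tv$true_value, rep(plogis(qlogis(0.15)), 15))
})

test_that("negative variances are rejected", {
  expect_error(sim_params(measures = list(
    low_birth_weight = list(sigma_county = -0.1))), "invalid")
})

test_that("realized within-state spread of log county rates matches sigma_county", {
  # moment oracle on a 10,000-county universe: the county random effect is
  # shared by all age groups, so log(true YPLL rate) = const + e_jk exactly
  prm <- sim_params(measures = list(
    premature_mortality = list(sigma_state = 0, sigma_county = 0.3)))
  out <- simulate_universe(J = 10, counties_per_state = 1000, params = prm,
                           seed = 8)
  tv <- out$truth$true_values %>%
    dplyr::filter(measure == "premature_mortality") %>%
    dplyr::group_by(state_index) %>%
    dplyr::summarise(s = sd(log(true_value)))
  expect_equal(mean(tv$s), 0.3, tolerance = 0.02)
})

test_that("true composite ranks are recomputable from true values alone", {
  out <- simulate_universe(J = 4, counties_per_state = 10, seed = 21)
  # independent recomputation: z-scores of true values, weighted sum, rank
  g <- out$universe$geography
  wide <- tidyr::pivot_wider(out$truth$true_values,
                             names_from = measure,
                             values_from = true_value) %>%
    dplyr::left_join(dplyr::select(g, state_index, county_index, county_id),
                     by = c("state_index", "county_index")) %>%
    dplyr::arrange(county_id)
  cfg <- measure_config()
  score <- rep(0, nrow(g))
  for (i in seq_len(nrow(cfg))) {
    x <- wide[[cfg$measure[i]]]
    score <- score + cfg$weight[i] * (x - mean(x)) / sd(x)
  }
  expect_equal(out$truth$true_composite$true_score, score)
  expect_identical(out$truth$true_composite$true_rank,
                   rank(score, ties.method = "first"))
  expect_setequal(out$truth$true_composite$true_rank, seq_len(nrow(g)))
})

test_that("censoring applies the reporting thresholds cell by cell", {
  out <- simulate_universe(J = 6, counties_per_state = 15, seed = 31)
  u <- out$universe
  uc <- apply_censoring(u)

  # count cells: suppressed iff events <= 5
  expect_identical(uc$low_birth_weight$suppressed,
                   u$low_birth_weight$events <= 5)
  expect_identical(uc$mortality$suppressed, u$mortality$deaths <= 5)
  expect_true(all(is.na(uc$mortality$deaths[uc$mortality$suppressed])))

  # survey cells: censored iff n < 50 or CI too wide
  expect_identical(
    uc$fair_poor_health$censored,
    u$fair_poor_health$n_respondents < 50 |
      (u$fair_poor_health$ci_high - u$fair_poor_health$ci_low) > 0.20)
  rel <- (u$poor_physical_days$ci_high - u$poor_physical_days$ci_low) /
    u$poor_physical_days$mean_days
  expect_identical(uc$poor_physical_days$censored,
                   u$poor_physical_days$n_respondents < 50 | rel > 1.0)

  # boundary cases: 5 events suppressed, 49 respondents censored,
  # 6 events / 51 respondents / narrow CI untouched
  lbw <- u$low_birth_weight
  lbw$events[1:2] <- c(5L, 6L)
  lbw$births[1:2] <- c(1000, 1000)
  fph <- u$fair_poor_health
  fph$n_respondents[1:3] <- c(49L, 51L, 51L)
  fph$prevalence[1:3] <- 0.3
  fph$ci_low[1:3] <- c(0.2, 0.2, 0.25)
  fph$ci_high[1:3] <- c(0.4, 0.41, 0.35)  # widths 0.2, 0.21, 0.10
  u2 <- u
  u2$low_birth_weight <- lbw
  u2$fair_poor_health <- fph
  uc2 <- apply_censoring(u2)
  expect_true(uc2$low_birth_weight$suppressed[1])
  expect_false(uc2$low_birth_weight$suppressed[2])
  expect_identical(uc2$fair_poor_health$censored[1:3],
                   c(TRUE, TRUE, FALSE))
})

test_that("censored fractions land in a realistic missing-data range", {
  out <- simulate_universe(J = 10, counties_per_state = 30, seed = 77)
  uc <- apply_censoring(out$universe)
  frac <- c(mean(uc$low_birth_weight$suppressed),
            mean(uc$fair_poor_health$censored),
            mean(uc$poor_physical_days$censored),
            mean(uc$poor_mental_days$censored))
  expect_true(all(frac > 0.005 & frac < 0.2))
})
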