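# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# mid-sized censored universe with model-1 fits, shared across files
fixture_fit_universe <- function() {
  memo("fit_universe", {
    out <- simulate_universe(J = 8, counties_per_state = 12, seed = 424)
    uc <- apply_censoring(out$universe)
    fits <- suppressWarnings(fit_all_measures(uc, "model1"))
    list(universe = uc, raw = out$universe, truth = out$truth, fits = fits)
  })
}

fixture_samples <- function() {
  memo("samples", {
    fx <- fixture_fit_universe()
    purrr::imap(fx$fits, function(f, ms)
      posterior_measure_samples(f, fx$universe, S = 400,
                                seed = 100 + match(ms, names(fx$fits))))
  })
}

# hand-built two-county log-normal fit with known variance components,
# for closed-form checks of the joint posterior
toy_lognormal_fit <- function(y = c(1.2, 0.8), v = c(0.04, 0.09),
                              beta = 1.0, sigma_county = 0.3,
                              sigma_state = 0) {
  counties <- tibble::tibble(state_index = c(1L, 2L),
                             county_index = c(1L, 1L),
                             county_id = c(1L, 2L))
  structure(list(
    measure = "poor_physical_days", family = "lognormal",
    model_form = "model1",
    beta = tibble::tibble(term = "(Intercept)", estimate = beta),
    sigma_state_hat = sigma_state, sigma_county_hat = sigma_county,
    loglik = NA_real_, converged = TRUE, n_obs = 2L,
    J = 2L, N = 2L, state_levels = c(1L, 2L),
    county_state = c(1L, 2L), counties = counties,
    eb_data = list(y = y, v = v, size = NULL, offset = NULL,
                   X_obs = matrix(1, 2, 1,
                                  dimnames = list(NULL, "(Intercept)")),
                   obs_state = c(1L, 2L), obs_county = c(1L, 2L),
                   X_pred = matrix(1, 2, 1,
                                   dimnames = list(NULL, "(Intercept)")),
                   pred_county = c(1L, 2L), pred_group = NULL),
    diagnostics = character()), class = "measure_fit")
}

# small Poisson toy (2 states x 3 counties, one count per county) with fixed
# variance components, used for the quadrature cross-check
toy_poisson_fit <- function(y = c(18L, 25L, 31L, 12L, 40L, 22L),
                            n = c(900, 1100, 1300, 700, 1600, 1000),
                            beta = log(0.022),
                            sigma_state = 0.3, sigma_county = 0.4) {
  counties <- tibble::tibble(state_index = rep(1:2, each = 3),
                             county_index = rep(1:3, 2),
                             county_id = 1:6)
  structure(list(
    measure = "premature_mortality", family = "poisson",
    model_form = "model1",
    beta = tibble::tibble(term = "(Intercept)", estimate = beta),
    sigma_state_hat = sigma_state, sigma_county_hat = sigma_county,
    loglik = NA_real_, converged = TRUE, n_obs = 6L,
    J = 2L, N = 6L, state_levels = c(1L, 2L),
    county_state = rep(1:2, each = 3), counties = counties,
    eb_data = list(y = y, offset = log(n), size = NULL, v = NULL,
                   X_obs = matrix(1, 6, 1,
                                  dimnames = list(NULL, "(Intercept)")),
                   obs_state = rep(1:2, each = 3), obs_county = 1:6,
                   X_pred = matrix(1, 6, 1,
                                   dimnames = list(NULL, "(Intercept)")),
                   pred_county = 1:6, pred_group = NULL),
    diagnostics = character()), class = "measure_fit")
}

# direct nested-quadrature marginal log-likelihood for the Poisson toy
quadrature_loglik_poisson <- function(y, n, beta, sigma_state, sigma_county,
                                      state_of) {
  county_lik <- function(yk, nk, eta0) {
    f <- function(u) dpois(yk, exp(eta0 + u) * nk) *
      dnorm(u, 0, sigma_county)
    integrate(f, -8 * sigma_county, 8 * sigma_county,
              rel.tol = 1e-12)$value
  }
  total <- 0
  for (j in unique(state_of)) {
    ks <- which(state_of == j)
    f_state <- Vectorize(function(uj) {
      prod(vapply(ks, function(k)
        county_lik(y[k], n[k], beta + uj), numeric(1))) *
        dnorm(uj, 0, sigma_state)
    })
    total <- total + log(integrate(f_state, -8 * sigma_state,
                                   8 * sigma_state,
                                   rel.tol = 1e-10)$value)
  }
  total
}

# posterior samples object built directly from a values matrix/array
make_samples <- function(values, measure = "fair_poor_health",
                         family = "binomial") {
  N <- dim(values)[2]
  structure(list(measure = measure, family = family, model_form = "model1",
                 values = values, S = dim(values)[1], seed = 0L,
                 counties = tibble::tibble(state_index = rep(1L, N),
                                           county_index = seq_len(N),
                                           county_id = seq_len(N))),
            class = "posterior_samples")
}

# minimal 2-state universe with controlled age-group populations; only the
# tables ypll_from_samples touches need to be meaningful
make_mortality_universe <- function(pop_g, pop_total) {
  N <- nrow(pop_g)
  out <- simulate_universe(J = 2, counties_per_state = N / 2, seed = 1)
  u <- out$universe
  u$geography$population <- pop_total
  u$mortality <- u$mortality %>%
    dplyr::arrange(state_index, county_index,
                   factor(age_group, levels = countyrank:::AGE_GROUPS)) %>%
    dplyr::mutate(population = as.vector(t(pop_g)))
  u
}

# direct death-by-death YPLL oracle for random configurations
ypll_oracle <- function(rates, pop_g, pop_total) {
  w <- 75 - c(0.5, 3, 10, 20, 30, 40, 50, 60, 70)
  S <- dim(rates)[1]; N <- dim(rates)[2]
  oracle <- matrix(0, S, N)
  for (k in seq_len(N)) {
    for (g in 1:9)
      oracle[, k] <- oracle[, k] + rates[, k, g] * pop_g[k, g] * w[g]
    oracle[, k] <- 1e5 * oracle[, k] / pop_total[k]
  }
  oracle
}
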