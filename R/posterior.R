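#' Empirical Bayes conditioning: joint posterior of effects given variances
#'
#' Conditions on the estimated variance parameters (the empirical Bayes
#' convention: their uncertainty is not propagated, which tends to make
#' downstream rank precision optimistic) and builds the multivariate normal
#' approximation to the joint posterior of the stacked vector
#' `(beta, e_1..e_J, e_11..e_Jm_J)`. The mode maximizes the joint
#' log-posterior (flat prior on `beta`, Gaussian priors on the random
#' effects with the plugged-in variances); the covariance is the inverse of
#' its negative Hessian at the mode.
#'
#' Counties contributing no data (fully suppressed or censored) have random
#' effect mode 0 and conditional variance `sigma_county^2` -- this is the
#' imputation mechanism: such counties are ranked from their prior
#' distribution, never assigned a point value.
#'
#' @param fit A converged `measure_fit`.
#' @param universe The universe the fit came from (county bookkeeping).
#' @return A `joint_posterior` object: `mode`, `covariance`, index map,
#'   family/link metadata and the county-level prediction design.
#' @export
eb_condition <- function(fit, universe = NULL) {
  if (!inherits(fit, "measure_fit")) abort("fit must be a measure_fit")
  if (!isTRUE(fit$converged))
    abort(paste("fit for", fit$measure, "did not converge"))
  ed <- fit$eb_data
  n <- length(ed$y)
  p <- ncol(ed$X_obs)
  offset <- ed$offset %||% rep(0, n)

  blocks <- list(beta = Matrix::Matrix(ed$X_obs, sparse = TRUE))
  pdiag <- rep(0, p)
  idx <- list(beta = seq_len(p))
  pos <- p
  has_state <- fit$sigma_state_hat > 0
  has_county <- fit$sigma_county_hat > 0
  if (has_state) {
    blocks$state <- state_Z(ed$obs_state, fit$state_levels, n)
    pdiag <- c(pdiag, rep(1 / fit$sigma_state_hat^2, fit$J))
    idx$state <- pos + seq_len(fit$J)
    pos <- pos + fit$J
  }
  if (has_county) {
    blocks$county <- county_Z(ed$obs_county, fit$N, n)
    pdiag <- c(pdiag, rep(1 / fit$sigma_county_hat^2, fit$N))
    idx$county <- pos + seq_len(fit$N)
    pos <- pos + fit$N
  }
  M <- do.call(cbind, unname(blocks))

  res <- newton_penalized(M, offset, ed$y, fit$family, ed$size, ed$v,
                          pdiag, theta0 = c(fit$beta$estimate,
                                            numeric(pos - p)))
  if (!res$converged)
    abort(paste("joint posterior mode search did not converge for",
                fit$measure))
  covariance <- tryCatch(as.matrix(Matrix::solve(res$H)),
                         error = function(e)
                           abort(paste0("singular joint Hessian for ",
                                        fit$measure,
                                        " (beta/state/county block): ",
                                        conditionMessage(e))))
  covariance <- (covariance + t(covariance)) / 2

  structure(list(
    measure = fit$measure, family = fit$family, model_form = fit$model_form,
    link = switch(fit$family, poisson = "log", binomial = "logit",
                  lognormal = "log"),
    mode = res$theta, covariance = covariance, index = idx,
    sigma_state = fit$sigma_state_hat, sigma_county = fit$sigma_county_hat,
    J = fit$J, N = fit$N, state_levels = fit$state_levels,
    county_state = fit$county_state, counties = fit$counties,
    X_pred = ed$X_pred, pred_county = ed$pred_county,
    pred_group = ed$pred_group, n_obs = fit$n_obs),
    class = "joint_posterior")
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat("<joint_posterior> ", x$measure, " (", x$family, ", ", x$model_form,
      ")\n  dimension ", length(x$mode), " = ",
      length(x$index$beta), " fixed + ",
      length(x$index$state %||% integer()), " state + ",
      length(x$index$county %||% integer()), " county effects\n", sep = "")
  invisible(x)
}

#' Draw joint posterior samples of county-level measure values
#'
#' Draws `S` multivariate normal samples from the joint posterior
#' approximation, pushes each through the county-level linear predictor and
#' the inverse link, and returns natural-scale county values: event rates
#' per person-year for the nine mortality age groups, proportions for
#' binomial measures, days per month for the mean-days measures.
#' Reproducible under a fixed seed.
#'
#' @param jp A `joint_posterior`.
#' @param S Number of samples (>= 100).
#' @param seed Integer seed (mandatory).
#' @return A `posterior_samples` object. For the Poisson measure `values` is
#'   an `S x N x 9` array (counties x age groups); otherwise an `S x N`
#'   matrix.
#' @export
draw_samples <- function(jp, S, seed) {
  if (!inherits(jp, "joint_posterior")) abort("jp must be a joint_posterior")
  if (S < 100) abort("S must be at least 100")
  if (missing(seed)) abort("seed is mandatory")
  d <- length(jp$mode)
  eg <- eigen(jp$covariance, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    abort("covariance not positive semidefinite after symmetrization")
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))

  set.seed(seed)
  theta <- jp$mode + L %*% matrix(rnorm(d * S), d, S)  # d x S

  n_pred <- nrow(jp$X_pred)
  A_blocks <- list(Matrix::Matrix(jp$X_pred, sparse = TRUE))
  if (!is.null(jp$index$state))
    A_blocks <- c(A_blocks, list(state_Z(
      jp$state_levels[jp$county_state[jp$pred_county]], jp$state_levels,
      n_pred)))
  if (!is.null(jp$index$county))
    A_blocks <- c(A_blocks, list(county_Z(jp$pred_county, jp$N, n_pred)))
  A <- do.call(cbind, A_blocks)
  eta <- as.matrix(A %*% theta)  # n_pred x S
  nat <- switch(jp$family,
                poisson = exp(eta),
                binomial = plogis(eta),
                lognormal = exp(eta))

  by_group <- !is.null(jp$pred_group)
  values <- if (by_group) {
    aperm(array(nat, dim = c(9, jp$N, S)), c(3, 2, 1))
  } else {
    t(nat)
  }
  structure(list(measure = jp$measure, family = jp$family,
                 model_form = jp$model_form, values = values,
                 S = S, seed = seed, counties = jp$counties,
                 age_groups = if (by_group) AGE_GROUPS),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", x$measure, ": S = ", x$S, ", N = ",
      nrow(x$counties), if (x$family == "poisson") " (9 age groups)",
      "\n", sep = "")
  invisible(x)
}

#' YPLL-75 posterior samples from age-group mortality samples
#'
#' Converts posterior samples of the nine age-group mortality rates into
#' years of potential life lost before age 75 per 100,000 population: each
#' death is weighted by `75 - age at death`, taking age at death as the age
#' group midpoint, so per sample and county
#' `YPLL = 100000 * sum_g rate_g * (75 - midpoint_g) * pop_g / pop_total`.
#' The result is crude (not age-standardized).
#'
#' @param samples `posterior_samples` from the Poisson mortality model
#'   (`S x N x 9` array).
#' @param universe The matching universe (age-group and total populations).
#' @param midpoints Age-at-death midpoints per group (configurable;
#'   default the interval midpoints 0.5, 3, 10, 20, ..., 70).
#' @return A `posterior_samples` object with an `S x N` matrix of YPLL-75
#'   rates per 100,000.
#' @export
ypll_from_samples <- function(samples, universe,
                              midpoints = AGE_MIDPOINTS) {
  if (samples$family != "poisson")
    abort("YPLL requires the Poisson mortality samples")
  if (length(dim(samples$values)) != 3 || dim(samples$values)[3] != 9)
    abort("mortality samples misaligned: expected S x N x 9 age groups")
  g <- universe$geography
  N <- nrow(g)
  if (dim(samples$values)[2] != N)
    abort("mortality samples misaligned with universe counties")
  mort <- universe$mortality %>%
    left_join(select(g, "state_index", "county_index", "county_id"),
              by = c("state_index", "county_index")) %>%
    mutate(age_group = factor(.data$age_group, levels = AGE_GROUPS)) %>%
    arrange(.data$county_id, .data$age_group)
  pop_g <- matrix(mort$population, nrow = N, ncol = 9, byrow = TRUE)
  w <- 75 - midpoints
  ypll <- matrix(0, samples$S, N)
  for (gi in seq_len(9)) {
    ypll <- ypll + sweep(samples$values[, , gi, drop = TRUE], 2,
                         w[gi] * pop_g[, gi] / g$population, `*`)
  }
  structure(list(measure = "premature_mortality", family = "poisson",
                 model_form = samples$model_form, values = 1e5 * ypll,
                 S = samples$S, seed = samples$seed,
                 counties = samples$counties, age_groups = NULL),
            class = "posterior_samples")
}

#' Posterior samples for one measure, end to end
#'
#' Convenience wrapper: [eb_condition()] then [draw_samples()], converting
#' mortality samples to YPLL-75 so every measure returns an `S x N` matrix
#' on its composite-ready natural scale.
#'
#' @inheritParams eb_condition
#' @inheritParams draw_samples
#' @param universe The universe the fit came from.
#' @return A `posterior_samples` object with an `S x N` `values` matrix.
#' @export
posterior_measure_samples <- function(fit, universe, S = 1000, seed) {
  jp <- eb_condition(fit, universe)
  smp <- draw_samples(jp, S, seed)
  if (fit$family == "poisson") smp <- ypll_from_samples(smp, universe)
  smp
}
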