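#' Effective binomial counts from a reported prevalence and its 95% CI
#'
#' Survey prevalence estimates arrive as a point estimate with 95%
#' confidence limits rather than raw counts. The implied standard error
#' `SE = (ci_high - ci_low) / (2 * 1.959964)` yields an effective denominator
#' `n_eff = p (1 - p) / SE^2` (rounded to the nearest integer, floored at 1)
#' and an effective numerator `round(p * n_eff)`, so the estimate can enter a
#' binomial likelihood.
#'
#' @param data Data frame with columns `prevalence`, `ci_low`, `ci_high`
#'   (optionally `censored`; censored rows are not allowed here).
#' @return The input with `events` and `denominator` columns appended.
#' @export
#' @examples
#' derive_effective_counts(
#'   tibble::tibble(prevalence = 0.2, ci_low = 0.12, ci_high = 0.28))
derive_effective_counts <- function(data) {
  stopifnot(is.data.frame(data))
  if ("censored" %in% names(data) && any(data$censored))
    abort("derive_effective_counts expects uncensored rows only")
  p <- data$prevalence
  if (any(p <= 0 | p >= 1))
    abort("effective counts undefined for prevalence 0 or 1 (degenerate SE)")
  se <- (data$ci_high - data$ci_low) / (2 * Z95)
  if (any(se <= 0))
    abort("nonpositive implied standard error (zero-width CI)")
  n_eff <- pmax(1, round(p * (1 - p) / se^2))
  data %>% mutate(events = round(p * n_eff),
                  denominator = as.integer(n_eff))
}

new_measure_fit <- function(measure, family, model_form, beta, sigma_state,
                            sigma_county, loglik, converged, n_obs, universe,
                            eb_data, diagnostics = character()) {
  g <- universe$geography
  state_levels <- sort(unique(g$state_index))
  structure(list(
    measure = measure, family = family, model_form = model_form,
    beta = beta, sigma_state_hat = sigma_state,
    sigma_county_hat = sigma_county, loglik = loglik,
    converged = converged, n_obs = n_obs,
    J = length(state_levels), N = nrow(g),
    state_levels = state_levels,
    county_state = match(g$state_index, state_levels),
    counties = select(g, "state_index", "county_index", "county_id"),
    eb_data = eb_data, diagnostics = diagnostics),
    class = "measure_fit")
}

#' @export
print.measure_fit <- function(x, ...) {
  cat("<measure_fit> ", x$measure, " (", x$family, ", ", x$model_form, ")\n",
      sep = "")
  cat("  sigma_state = ", signif(x$sigma_state_hat, 4),
      ", sigma_county = ", signif(x$sigma_county_hat, 4), "\n", sep = "")
  cat("  logLik = ", round(x$loglik, 2), ", n_obs = ", x$n_obs,
      ", converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

glmer_converged <- function(fit) {
  isTRUE(fit@optinfo$conv$opt == 0)
}

# lme4/metafor drop rank-deficient fixed-effect columns (e.g. a category
# present only in suppressed counties); keep our design matrices aligned
# with the coefficients actually estimated.
align_fixed <- function(X, keep) {
  missing <- setdiff(keep, colnames(X))
  if (length(missing) > 0)
    abort(paste("internal design mismatch; unknown terms:",
                paste(missing, collapse = ", ")))
  dropped <- setdiff(colnames(X), keep)
  if (length(dropped) > 0)
    warn(paste("fixed-effect column(s) dropped as inestimable:",
               paste(dropped, collapse = ", ")))
  X[, keep, drop = FALSE]
}

vc_sigmas <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  c(state = vc$sdcor[vc$grp == "state"],
    county = vc$sdcor[vc$grp == "county"])
}

check_multistate <- function(universe) {
  if (n_states(universe) < 2)
    abort("state-level variance is unidentifiable with a single state (J >= 2 required)")
}

fixed_rhs <- function(first, terms) {
  paste(c(first, terms), collapse = " + ")
}

#' Fit the nested mixed model for one measure
#'
#' Maximum-likelihood fits of the two-level generalized linear mixed model
#' `link(rate_jk) = x_jk' beta + e_j + e_jk`, `e_j ~ N(0, sigma_state^2)`,
#' `e_jk ~ N(0, sigma_county^2)`, for a single measure:
#'
#' * `premature_mortality` -- Poisson log-link on the nine age-group death
#'   counts with offset `log(person-years)`; model 1's intercept expands to
#'   nine age-group intercepts sharing one county random effect.
#' * `low_birth_weight`, `fair_poor_health` -- binomial logit; survey
#'   prevalence is first converted to effective counts via
#'   [derive_effective_counts()].
#' * `poor_physical_days`, `poor_mental_days` -- linear mixed model on
#'   `log(mean_days)` with known per-county sampling variances (from the
#'   reported CI by the delta method) as inverse-variance weights.
#'
#' Suppressed and censored cells are excluded from the likelihood; the
#' counties themselves stay in the universe and are imputed downstream
#' through their random effects. Poisson/binomial models are estimated by
#' Laplace-approximate ML ([lme4::glmer()]); the log-normal model by exact
#' Gaussian ML with fixed sampling variances ([metafor::rma.mv()]).
#'
#' @param universe A `county_universe`.
#' @param measure One of the five measure names (see [measure_config()]).
#' @param model_form `"model1"` (intercept only) or `"model2"` (demographic
#'   covariates).
#' @return A `measure_fit` object; see [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_measure <- function(universe, measure = MEASURE_NAMES,
                        model_form = c("model1", "model2")) {
  measure <- match.arg(measure)
  model_form <- match.arg(model_form)
  check_multistate(universe)
  switch(MEASURE_FAMILIES[[measure]],
         poisson = fit_poisson(universe, model_form),
         binomial = fit_binomial(universe, measure, model_form),
         lognormal = fit_lognormal(universe, measure, model_form))
}

#' @rdname fit_measure
#' @export
fit_poisson <- function(universe, model_form = c("model1", "model2")) {
  model_form <- match.arg(model_form)
  check_multistate(universe)
  des <- build_design(universe, model_form)
  mt <- measure_table(universe, "premature_mortality") %>%
    filter(!.data$suppressed) %>%
    left_join(des$cov_data, by = "county_id") %>%
    mutate(age_group = factor(.data$age_group, levels = AGE_GROUPS),
           state = factor(.data$state_index),
           county = factor(.data$county_id),
           lpop = log(.data$population))
  if (nrow(mt) == 0) abort("no unsuppressed mortality cells to fit")

  ff <- as.formula(paste("deaths ~", fixed_rhs("0 + age_group", des$terms),
                         "+ (1 | state) + (1 | county)"))
  fit <- lme4::glmer(ff, data = mt, family = stats::poisson(),
                     offset = mt$lpop,
                     control = lme4::glmerControl(
                       optimizer = "bobyqa", calc.derivs = FALSE,
                       check.conv.singular = "ignore",
                       optCtrl = list(maxfun = 1e5)))
  sig <- vc_sigmas(fit)
  beta_hat <- lme4::fixef(fit)
  X_obs <- align_fixed(model.matrix(
    as.formula(paste("~", fixed_rhs("0 + age_group", des$terms))), mt),
    names(beta_hat))

  # prediction design: every county x all 9 age groups, county-major order
  N <- n_counties(universe)
  pred <- des$cov_data[rep(seq_len(N), each = 9), , drop = FALSE] %>%
    mutate(age_group = factor(rep(AGE_GROUPS, N), levels = AGE_GROUPS))
  X_pred <- suppressWarnings(align_fixed(model.matrix(
    as.formula(paste("~", fixed_rhs("0 + age_group", des$terms))), pred),
    names(beta_hat)))

  new_measure_fit(
    measure = "premature_mortality", family = "poisson",
    model_form = model_form,
    beta = tibble(term = names(beta_hat), estimate = unname(beta_hat)),
    sigma_state = unname(sig["state"]), sigma_county = unname(sig["county"]),
    loglik = as.numeric(logLik(fit)), converged = glmer_converged(fit),
    n_obs = nrow(mt), universe = universe,
    eb_data = list(y = mt$deaths, offset = mt$lpop, size = NULL, v = NULL,
                   X_obs = X_obs, obs_state = mt$state_index,
                   obs_county = mt$county_id,
                   X_pred = X_pred, pred_county = rep(seq_len(N), each = 9),
                   pred_group = rep(AGE_GROUPS, N)),
    diagnostics = unlist(fit@optinfo$conv$lme4$messages) %||% character())
}

#' @rdname fit_measure
#' @export
fit_binomial <- function(universe,
                         measure = c("low_birth_weight", "fair_poor_health"),
                         model_form = c("model1", "model2")) {
  measure <- match.arg(measure)
  model_form <- match.arg(model_form)
  check_multistate(universe)
  des <- build_design(universe, model_form)

  tbl <- measure_table(universe, measure)
  if (measure == "low_birth_weight") {
    obs <- tbl %>% filter(!.data$suppressed) %>%
      mutate(y = .data$events, size = .data$births)
  } else {
    obs <- tbl %>% filter(!.data$censored)
    degenerate <- obs$prevalence <= 0 | obs$prevalence >= 1
    if (any(degenerate)) {
      warn(paste0(sum(degenerate), " fair_poor_health cell(s) with ",
                  "prevalence 0 or 1 excluded (effective counts undefined)"))
      obs <- obs[!degenerate, , drop = FALSE]
    }
    obs <- derive_effective_counts(obs) %>%
      mutate(y = .data$events, size = .data$denominator)
  }
  if (nrow(obs) == 0) abort(paste("no observed cells for", measure))
  obs <- obs %>%
    left_join(des$cov_data, by = "county_id") %>%
    mutate(state = factor(.data$state_index),
           county = factor(.data$county_id))

  ff <- as.formula(paste("cbind(y, size - y) ~", fixed_rhs("1", des$terms),
                         "+ (1 | state) + (1 | county)"))
  ctrl <- function(tol) lme4::glmerControl(
    optimizer = "bobyqa", calc.derivs = FALSE,
    check.conv.singular = "ignore", check.response.not.const = "ignore",
    tolPwrss = tol, optCtrl = list(maxfun = 1e5))
  relaxed <- FALSE
  fit <- tryCatch(
    lme4::glmer(ff, data = obs, family = stats::binomial(),
                control = ctrl(1e-7)),
    error = function(e) {
      # near-degenerate universes (huge effective counts, near-constant
      # response) can stall PIRLS at the default tolerance
      relaxed <<- TRUE
      tryCatch(
        lme4::glmer(ff, data = obs, family = stats::binomial(),
                    control = ctrl(1e-3)),
        error = function(e2) NULL)
    })
  if (is.null(fit)) {
    # PIRLS cannot handle this configuration at all: maximize the Laplace
    # marginal likelihood directly with the package's own machinery
    X_obs <- model.matrix(as.formula(paste("~", fixed_rhs("1", des$terms))),
                          obs)
    state_levels <- sort(unique(universe$geography$state_index))
    ml <- ml_laplace("binomial", y = obs$y, X_obs = X_obs,
                     size = obs$size, obs_state = obs$state_index,
                     state_levels = state_levels,
                     obs_county = obs$county_id,
                     N = n_counties(universe))
    X_pred <- suppressWarnings(align_fixed(des$X, colnames(X_obs)))
    return(new_measure_fit(
      measure = measure, family = "binomial", model_form = model_form,
      beta = tibble(term = names(ml$beta), estimate = unname(ml$beta)),
      sigma_state = ml$sigma_state, sigma_county = ml$sigma_county,
      loglik = ml$loglik, converged = ml$converged,
      n_obs = nrow(obs), universe = universe,
      eb_data = list(y = obs$y, size = obs$size, offset = NULL, v = NULL,
                     X_obs = X_obs, obs_state = obs$state_index,
                     obs_county = obs$county_id,
                     X_pred = X_pred,
                     pred_county = seq_len(n_counties(universe)),
                     pred_group = NULL),
      diagnostics = "fitted by internal Laplace ML (PIRLS unavailable)"))
  }
  sig <- vc_sigmas(fit)
  beta_hat <- lme4::fixef(fit)
  X_obs <- align_fixed(
    model.matrix(as.formula(paste("~", fixed_rhs("1", des$terms))), obs),
    names(beta_hat))
  X_pred <- suppressWarnings(align_fixed(des$X, names(beta_hat)))

  new_measure_fit(
    measure = measure, family = "binomial", model_form = model_form,
    beta = tibble(term = names(beta_hat), estimate = unname(beta_hat)),
    sigma_state = unname(sig["state"]), sigma_county = unname(sig["county"]),
    loglik = as.numeric(logLik(fit)), converged = glmer_converged(fit),
    n_obs = nrow(obs), universe = universe,
    eb_data = list(y = obs$y, size = obs$size, offset = NULL, v = NULL,
                   X_obs = X_obs, obs_state = obs$state_index,
                   obs_county = obs$county_id,
                   X_pred = X_pred,
                   pred_county = seq_len(n_counties(universe)),
                   pred_group = NULL),
    diagnostics = c(if (relaxed) "PIRLS tolerance relaxed to 1e-3",
                    unlist(fit@optinfo$conv$lme4$messages) %||% character()))
}

#' @rdname fit_measure
#' @export
fit_lognormal <- function(universe,
                          measure = c("poor_physical_days",
                                      "poor_mental_days"),
                          model_form = c("model1", "model2")) {
  measure <- match.arg(measure)
  model_form <- match.arg(model_form)
  check_multistate(universe)
  des <- build_design(universe, model_form)

  obs <- measure_table(universe, measure) %>% filter(!.data$censored)
  if (nrow(obs) == 0) abort(paste("no observed cells for", measure))
  # delta method: Var(log Xbar) ~= Var(Xbar) / Xbar^2
  se_nat <- (obs$ci_high - obs$ci_low) / (2 * Z95)
  v <- se_nat^2 / obs$mean_days^2
  if (any(v <= 0))
    abort(paste("nonpositive derived sampling variance for counties:",
                bad_keys(obs, v <= 0)))
  obs <- obs %>%
    mutate(y = log(.data$mean_days), v = v,
           state = factor(.data$state_index),
           county = factor(.data$county_id)) %>%
    left_join(des$cov_data, by = "county_id")

  args <- list(yi = quote(y), V = quote(v), random = ~ 1 | state / county,
               data = obs, method = "ML", sparse = TRUE)
  if (length(des$terms) > 0)
    args$mods <- as.formula(paste("~", paste(des$terms, collapse = " + ")))
  fit <- tryCatch(do.call(metafor::rma.mv, args), error = function(e) e)
  X_obs <- model.matrix(as.formula(paste("~", fixed_rhs("1", des$terms))), obs)
  if (inherits(fit, "error")) {
    return(new_measure_fit(
      measure = measure, family = "lognormal", model_form = model_form,
      beta = tibble(term = colnames(X_obs), estimate = NA_real_),
      sigma_state = NA_real_, sigma_county = NA_real_, loglik = NA_real_,
      converged = FALSE, n_obs = nrow(obs), universe = universe,
      eb_data = NULL, diagnostics = conditionMessage(fit)))
  }
  beta_hat <- as.vector(fit$beta)
  terms_hat <- sub("^intrcpt$", "(Intercept)", rownames(fit$beta))
  X_obs <- align_fixed(X_obs, terms_hat)
  X_pred <- suppressWarnings(align_fixed(des$X, terms_hat))

  new_measure_fit(
    measure = measure, family = "lognormal", model_form = model_form,
    beta = tibble(term = terms_hat, estimate = beta_hat),
    sigma_state = sqrt(fit$sigma2[1]), sigma_county = sqrt(fit$sigma2[2]),
    loglik = as.numeric(logLik(fit)), converged = TRUE,
    n_obs = nrow(obs), universe = universe,
    eb_data = list(y = obs$y, v = obs$v, size = NULL, offset = NULL,
                   X_obs = X_obs, obs_state = obs$state_index,
                   obs_county = obs$county_id,
                   X_pred = X_pred,
                   pred_county = seq_len(n_counties(universe)),
                   pred_group = NULL))
}

#' Fit all five measures
#'
#' @param universe A `county_universe`.
#' @param model_form `"model1"` or `"model2"`.
#' @return A named list of `measure_fit` objects.
#' @export
fit_all_measures <- function(universe, model_form = c("model1", "model2")) {
  model_form <- match.arg(model_form)
  setNames(lapply(MEASURE_NAMES, fit_measure, universe = universe,
                  model_form = model_form), MEASURE_NAMES)
}
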