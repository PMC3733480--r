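#' Posterior predictive replicate datasets for one measure
#'
#' For each posterior sample and each county that contributed observed data,
#' draws a replicate observation from the measure's sampling distribution at
#' that sample's county value and the county's reported denominator:
#' Poisson deaths per age group (converted to a replicate YPLL-75 rate),
#' binomial events over the reported (or effective) denominator (converted
#' to a proportion), or a normal replicate of the log mean-days with the
#' county's sampling SD (converted back to days). Replicates are generated
#' only for counties contributing observed data; everything is on the
#' natural measure scale, matching the observed vector returned alongside.
#'
#' @param samples `posterior_samples` for the measure. For premature
#'   mortality pass the age-group samples (the `S x N x 9` array from
#'   [draw_samples()]), not the YPLL matrix.
#' @param universe The universe (denominators and observed values).
#' @param seed Integer seed.
#' @return A `ppc_replicates` list: `measure`, `observed` (length-n vector),
#'   `replicates` (`S x n` matrix), `counties`.
#' @export
replicate_datasets <- function(samples, universe, seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  ms <- samples$measure
  S <- samples$S
  g <- universe$geography

  if (ms == "premature_mortality") {
    if (length(dim(samples$values)) != 3)
      abort("pass the age-group mortality samples, not the YPLL matrix")
    mort <- universe$mortality %>%
      left_join(select(g, "state_index", "county_index", "county_id"),
                by = c("state_index", "county_index")) %>%
      mutate(age_group = factor(.data$age_group, levels = AGE_GROUPS)) %>%
      arrange(.data$county_id, .data$age_group)
    full <- mort %>% group_by(.data$county_id) %>%
      summarise(ok = !any(.data$suppressed)) %>% filter(.data$ok)
    keep <- full$county_id
    if (length(keep) == 0) abort("no county has all 9 age groups observed")
    pop_g <- matrix(mort$population, nrow = nrow(g), ncol = 9, byrow = TRUE)
    dth_g <- matrix(mort$deaths, nrow = nrow(g), ncol = 9, byrow = TRUE)
    w <- 75 - AGE_MIDPOINTS
    observed <- 1e5 * as.vector(dth_g[keep, ] %*% w) / g$population[keep]
    reps <- matrix(0, S, length(keep))
    for (gi in seq_len(9)) {
      lam <- samples$values[, keep, gi, drop = FALSE]
      dim(lam) <- dim(lam)[1:2]
      lam <- sweep(lam, 2, pop_g[keep, gi], `*`)
      y <- matrix(rpois(length(lam), lam), nrow = S)
      reps <- reps + w[gi] * y
    }
    reps <- sweep(reps, 2, 1e5 / g$population[keep], `*`)
    counties <- g[match(keep, g$county_id),
                  c("state_index", "county_index", "county_id")]
  } else if (ms == "low_birth_weight") {
    tbl <- measure_table(universe, ms) %>% filter(!.data$suppressed)
    if (nrow(tbl) == 0) abort("no observed low-birth-weight counties")
    keep <- tbl$county_id
    observed <- tbl$events / tbl$births
    p <- samples$values[, keep, drop = FALSE]
    y <- matrix(rbinom(length(p), rep(tbl$births, each = S), p), nrow = S)
    reps <- sweep(y, 2, tbl$births, `/`)
    counties <- select(tbl, "state_index", "county_index", "county_id")
  } else if (ms == "fair_poor_health") {
    tbl <- measure_table(universe, ms) %>% filter(!.data$censored) %>%
      filter(.data$prevalence > 0, .data$prevalence < 1) %>%
      derive_effective_counts()
    if (nrow(tbl) == 0) abort("no observed fair/poor-health counties")
    keep <- tbl$county_id
    observed <- tbl$prevalence
    p <- samples$values[, keep, drop = FALSE]
    y <- matrix(rbinom(length(p), rep(tbl$denominator, each = S), p),
                nrow = S)
    reps <- sweep(y, 2, tbl$denominator, `/`)
    counties <- select(tbl, "state_index", "county_index", "county_id")
  } else {
    tbl <- measure_table(universe, ms) %>% filter(!.data$censored)
    if (nrow(tbl) == 0) abort(paste("no observed counties for", ms))
    keep <- tbl$county_id
    s_log <- (tbl$ci_high - tbl$ci_low) / (2 * Z95) / tbl$mean_days
    observed <- tbl$mean_days
    mu <- log(samples$values[, keep, drop = FALSE])
    reps <- exp(mu + matrix(rnorm(length(mu), 0, rep(s_log, each = S)),
                            nrow = S))
    counties <- select(tbl, "state_index", "county_index", "county_id")
  }
  structure(list(measure = ms, observed = observed, replicates = reps,
                 counties = counties, seed = seed),
            class = "ppc_replicates")
}

#' Posterior predictive p-value for the across-county IQR
#'
#' The discrepancy statistic is the interquartile range of the measure's
#' distribution across counties (linear-interpolation quantiles), computed
#' on the observed data and within each replicate dataset. The two-sided
#' posterior predictive p-value is
#' `2 * min(Pr(IQR_rep >= IQR_obs), Pr(IQR_rep <= IQR_obs))` (capped at 1);
#' the model is flagged adequate when `ppp >= 0.05`. A small p-value means
#' the observed spread across counties is unlike what the fitted model
#' regenerates -- poor fit.
#'
#' @param observed_iqr Observed IQR (scalar).
#' @param replicate_iqrs Vector of replicate IQRs (>= 100).
#' @param measure Optional measure name carried into the result.
#' @return A `ppc_result` tibble (one row): `measure`, `observed_iqr`,
#'   `ppp_value`, `adequate`, with the replicate IQRs as an attribute.
#' @export
ppp_value <- function(observed_iqr, replicate_iqrs, measure = NA_character_) {
  if (length(replicate_iqrs) < 100)
    abort("at least 100 replicate IQRs required")
  p_hi <- mean(replicate_iqrs >= observed_iqr)
  p_lo <- mean(replicate_iqrs <= observed_iqr)
  ppp <- min(1, 2 * min(p_hi, p_lo))
  out <- tibble(measure = measure, observed_iqr = observed_iqr,
                median_replicate_iqr = median(replicate_iqrs),
                ppp_value = ppp, adequate = ppp >= 0.05)
  structure(out, class = c("ppc_result", class(out)),
            replicate_iqrs = replicate_iqrs)
}

#' Posterior predictive check for one measure
#'
#' Generates replicate datasets and scores the IQR discrepancy.
#'
#' @inheritParams replicate_datasets
#' @return A `ppc_result` tibble row; see [ppp_value()].
#' @export
ppc_check <- function(samples, universe, seed) {
  reps <- replicate_datasets(samples, universe, seed)
  ppp_value(IQR(reps$observed, type = 7),
            apply(reps$replicates, 1, IQR, type = 7),
            measure = reps$measure)
}
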