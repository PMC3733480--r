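#' Default generative parameters for a synthetic county universe
#'
#' The generator draws from the same two-level model the package fits:
#' for each measure, a state effect `e_j ~ N(0, sigma_state^2)` and a county
#' effect `e_jk ~ N(0, sigma_county^2)` enter a linear predictor on the link
#' scale, and observations are drawn from the measure's family. Defaults are
#' chosen to resemble US county data: log-normal populations (expressed as
#' person-years over the multi-year reporting window, median 75,000 -- about
#' 25,000 residents over three years -- with a heavy right tail, so genuinely
#' small counties exist), a realistic
#' all-cause mortality age curve over the nine age groups, baseline
#' fair/poor-health prevalence 15%, low-birth-weight prevalence 8%, and
#' mean poor physical/mental health days near 3.5 per month.
#'
#' @param model_form `"model1"` (intercept-only truth) or `"model2"`
#'   (demographic covariate effects enter every measure's linear predictor).
#' @param covariate_scale Multiplier on the default covariate effects
#'   (model-2 universes only); larger values give universes whose
#'   between-county variation is more covariate-driven.
#' @param ... Named overrides merged into the default list (e.g.
#'   `population = list(meanlog = log(5e4), sdlog = 1)` or
#'   `measures = list(fair_poor_health = list(sigma_county = 0))`).
#'
#' @return A named list of generative parameters.
#' @export
sim_params <- function(model_form = c("model1", "model2"),
                       covariate_scale = 1, ...) {
  model_form <- match.arg(model_form)
  p <- list(
    model_form = model_form,
    # person-years over the multi-year reporting window (~25k residents x 3y)
    population = list(meanlog = log(75000), sdlog = 1.2, min = 750),
    # fraction of total population in each of the 9 age groups (<75 only)
    age_fractions = c(0.013, 0.052, 0.130, 0.140, 0.130, 0.130,
                      0.145, 0.120, 0.075),
    # annual all-cause death rates per person-year by age group
    age_log_rates = log(c(0.0065, 3.0e-4, 1.5e-4, 8.0e-4, 1.0e-3,
                          2.0e-3, 4.3e-3, 9.0e-3, 2.15e-2)),
    brfss_rate = 0.004,   # survey respondents per person-year of population
    births_rate = 0.013,  # live births per person-year of population
    days_cv = 1.9,        # person-level CV of poor-health days
    measures = list(
      # cell_sd: extra log-scale noise per county x age-group cell, beyond
      # the shared county effect -- 0 keeps the generator matched to the
      # fitted model; > 0 injects overdispersion the Poisson fit cannot see
      premature_mortality = list(sigma_state = 0.10, sigma_county = 0.25,
                                 cell_sd = 0),
      fair_poor_health = list(beta0 = qlogis(0.15), sigma_state = 0.15,
                              sigma_county = 0.25),
      poor_physical_days = list(beta0 = log(3.7), sigma_state = 0.08,
                                sigma_county = 0.15),
      poor_mental_days = list(beta0 = log(3.4), sigma_state = 0.08,
                              sigma_county = 0.15),
      low_birth_weight = list(beta0 = qlogis(0.08), sigma_state = 0.08,
                              sigma_county = 0.12)),
    covariate_scale = covariate_scale,
    # link-scale effects, adverse direction positive; category 1 / low /
    # large_metro are references
    covariate_effects = list(
      race_black  = c(medium = 0.08, high = 0.20),
      race_asian  = c(medium = -0.05, high = -0.10),
      race_amind  = c(medium = 0.06, high = 0.15),
      race_latino = c(medium = -0.03, high = -0.06),
      urbanization = c(small_metro = 0.05, rural = 0.12),
      pct_female  = c("2" = 0.02, "3" = 0.04, "4" = 0.06),
      pct_under18 = c("2" = -0.02, "3" = -0.04, "4" = -0.06),
      pct_over64  = c("2" = 0.05, "3" = 0.10, "4" = 0.15)),
    demographic_probs = list(
      race_black  = c(0.60, 0.32, 0.08),
      race_asian  = c(0.80, 0.15, 0.05),
      race_amind  = c(0.78, 0.16, 0.06),
      race_latino = c(0.55, 0.35, 0.10),
      urbanization = c(0.20, 0.35, 0.45),
      pct_female  = c(0.10, 0.40, 0.40, 0.10),
      pct_under18 = c(0.15, 0.35, 0.35, 0.15),
      pct_over64  = c(0.15, 0.35, 0.35, 0.15))
  )
  over <- list(...)
  if (length(over) > 0) p <- modifyList(p, over)
  for (m in names(p$measures)) {
    s <- p$measures[[m]]
    if (any(c(s$sigma_state, s$sigma_county) < 0))
      abort(paste("invalid (negative) variance for measure", m))
  }
  p
}

covariate_shift <- function(demographics, params) {
  if (params$model_form != "model2") return(rep(0, nrow(demographics)))
  eff <- params$covariate_effects
  shift <- rep(0, nrow(demographics))
  for (cov in names(eff)) {
    lev <- as.character(demographics[[cov]])
    add <- eff[[cov]][lev]
    add[is.na(add)] <- 0  # reference level
    shift <- shift + add
  }
  shift * params$covariate_scale
}

#' Simulate a county universe with known truth
#'
#' Draws a full county universe -- populations, demographics, age-group death
#' counts, low-birth-weight counts, survey prevalence with confidence limits,
#' and reported mean poor-health days -- from the nested state/county
#' random-effects model, and returns it together with a `truth_record`
#' holding every generated quantity (effects, true rates, true composite
#' ranks). The universe is returned uncensored; apply the reporting rules
#' with [apply_censoring()].
#'
#' @param J Number of states (>= 2).
#' @param counties_per_state A single count, or a length-2 range from which
#'   each state's county count is drawn uniformly.
#' @param params Generative parameters from [sim_params()].
#' @param seed Integer seed; the same seed reproduces the universe exactly.
#'
#' @return A list with elements `universe` (a `county_universe`) and `truth`
#'   (a `truth_record`: `params`, `state_effects`, `county_effects`,
#'   `true_values` in natural units per county and measure,
#'   `true_age_rates`, and `true_composite` with `true_rank`).
#' @export
simulate_universe <- function(J, counties_per_state, params = sim_params(),
                              seed = 1) {
  if (J < 2) abort("J must be >= 2")
  set.seed(seed)
  m_j <- if (length(counties_per_state) == 1) {
    rep(as.integer(counties_per_state), J)
  } else {
    sample(seq(min(counties_per_state), max(counties_per_state)), J,
           replace = TRUE)
  }
  if (any(m_j < 1)) abort("each state needs at least one county")

  geography <- tibble(
    state_index = rep(seq_len(J), m_j),
    county_index = unlist(lapply(m_j, seq_len)),
    state_label = sprintf("S%02d", rep(seq_len(J), m_j)),
    county_label = sprintf("S%02d-C%03d", rep(seq_len(J), m_j),
                           unlist(lapply(m_j, seq_len))),
    population = pmax(params$population$min,
                      round(rlnorm(sum(m_j), params$population$meanlog,
                                   params$population$sdlog))))
  N <- nrow(geography)

  draw_cat <- function(probs, levels) {
    factor(levels[sample.int(length(levels), N, replace = TRUE, prob = probs)],
           levels = levels)
  }
  dp <- params$demographic_probs
  demographics <- tibble(
    state_index = geography$state_index,
    county_index = geography$county_index,
    race_black = draw_cat(dp$race_black, RACE_LEVELS),
    race_asian = draw_cat(dp$race_asian, RACE_LEVELS),
    race_amind = draw_cat(dp$race_amind, RACE_LEVELS),
    race_latino = draw_cat(dp$race_latino, RACE_LEVELS),
    urbanization = draw_cat(dp$urbanization, URBAN_LEVELS),
    pct_female = draw_cat(dp$pct_female, QUARTER_LEVELS),
    pct_under18 = draw_cat(dp$pct_under18, QUARTER_LEVELS),
    pct_over64 = draw_cat(dp$pct_over64, QUARTER_LEVELS))
  cov_shift <- covariate_shift(demographics, params)

  state_effects <- county_effects <- true_values <- list()
  true_age_rates <- NULL
  mortality <- lbw <- fph <- ppd <- pmd <- NULL

  for (ms in MEASURE_NAMES) {
    sp <- params$measures[[ms]]
    e_j <- rnorm(J, 0, sp$sigma_state)
    e_jk <- rnorm(N, 0, sp$sigma_county)
    eta_re <- e_j[geography$state_index] + e_jk + cov_shift
    state_effects[[ms]] <- tibble(measure = ms, state_index = seq_len(J),
                                  e_state = e_j)
    county_effects[[ms]] <- tibble(measure = ms,
                                   state_index = geography$state_index,
                                   county_index = geography$county_index,
                                   e_county = e_jk)

    if (ms == "premature_mortality") {
      pop_g <- outer(geography$population, params$age_fractions)
      pop_g <- matrix(pmax(1, round(pop_g)), nrow = N)
      rate_g <- exp(outer(eta_re, params$age_log_rates, "+") +
                      matrix(rnorm(N * 9, 0, sp$cell_sd %||% 0), N, 9))
      deaths <- matrix(rpois(N * 9, rate_g * pop_g), N, 9)
      deaths <- pmin(deaths, pop_g)
      mortality <- tibble(
        state_index = rep(geography$state_index, each = 9),
        county_index = rep(geography$county_index, each = 9),
        age_group = rep(AGE_GROUPS, N),
        deaths = as.integer(t(deaths)),
        population = as.vector(t(pop_g)),
        suppressed = FALSE)
      true_age_rates <- tibble(
        state_index = rep(geography$state_index, each = 9),
        county_index = rep(geography$county_index, each = 9),
        age_group = rep(AGE_GROUPS, N),
        true_rate = as.vector(t(rate_g)))
      w <- 75 - AGE_MIDPOINTS
      ypll <- 1e5 * rowSums(rate_g * sweep(pop_g, 2, w, "*")) /
        geography$population
      tv <- ypll
    } else if (ms == "low_birth_weight") {
      births <- pmax(1, round(params$births_rate * geography$population))
      p <- plogis(sp$beta0 + eta_re)
      events <- rbinom(N, births, p)
      lbw <- tibble(state_index = geography$state_index,
                    county_index = geography$county_index,
                    births = births, events = as.integer(events),
                    suppressed = FALSE)
      tv <- p
    } else if (ms == "fair_poor_health") {
      n <- pmax(1, round(params$brfss_rate * geography$population))
      p <- plogis(sp$beta0 + eta_re)
      events <- rbinom(N, n, p)
      phat <- events / n
      se <- sqrt(phat * (1 - phat) / n)
      # reported to fixed precision, as survey extracts arrive
      fph <- tibble(state_index = geography$state_index,
                    county_index = geography$county_index,
                    prevalence = round(phat, 6),
                    ci_low = round(pmax(0, phat - Z95 * se), 6),
                    ci_high = round(pmin(1, phat + Z95 * se), 6),
                    n_respondents = as.integer(n),
                    censored = FALSE)
      tv <- p
    } else {  # poor_physical_days / poor_mental_days
      n <- pmax(1, round(params$brfss_rate * geography$population))
      eta <- sp$beta0 + eta_re
      s_log <- params$days_cv / sqrt(n)  # sampling SD of log reported mean
      reported <- pmin(30, exp(rnorm(N, eta, s_log)))
      se <- reported * s_log
      tb <- tibble(state_index = geography$state_index,
                   county_index = geography$county_index,
                   mean_days = round(reported, 6),
                   ci_low = round(pmax(reported * 0.01,
                                       reported - Z95 * se), 6),
                   ci_high = round(reported + Z95 * se, 6),
                   n_respondents = as.integer(n),
                   censored = FALSE)
      if (ms == "poor_physical_days") ppd <- tb else pmd <- tb
      tv <- exp(eta)
    }
    true_values[[ms]] <- tibble(state_index = geography$state_index,
                                county_index = geography$county_index,
                                measure = ms, true_value = tv)
  }

  universe <- county_universe(geography, demographics, mortality, lbw,
                              fph, ppd, pmd)
  tv_long <- bind_rows(true_values)
  truth <- structure(list(
    params = params, seed = seed,
    state_effects = bind_rows(state_effects),
    county_effects = bind_rows(county_effects),
    true_values = tv_long,
    true_age_rates = true_age_rates,
    true_composite = true_composite_ranks(tv_long, universe)),
    class = "truth_record")
  list(universe = universe, truth = truth)
}

#' Recompute true composite scores and ranks from true values
#'
#' The bookkeeping oracle for the generator: the true composite health
#' outcomes score is the weighted sum of across-county z scores of the true
#' per-measure values (all measures adverse, so higher = worse), and the
#' true rank is its ascending rank (1 = healthiest), ties broken by county
#' order.
#'
#' @param true_values Long tibble with `state_index`, `county_index`,
#'   `measure`, `true_value` (as in a `truth_record`).
#' @param universe The matching universe (for county ordering and weights).
#' @return Tibble: county keys, `true_score`, `true_rank`.
#' @export
true_composite_ranks <- function(true_values, universe) {
  g <- universe$geography
  wts <- setNames(universe$measures$weight, universe$measures$measure)
  wide <- true_values %>%
    left_join(select(g, "state_index", "county_index", "county_id"),
              by = c("state_index", "county_index")) %>%
    arrange(.data$county_id)
  vals <- matrix(NA_real_, nrow = nrow(g), ncol = length(MEASURE_NAMES),
                 dimnames = list(NULL, MEASURE_NAMES))
  for (ms in MEASURE_NAMES) {
    v <- wide %>% filter(.data$measure == ms)
    vals[v$county_id, ms] <- v$true_value
  }
  z <- scale(vals)
  score <- as.vector(z %*% wts[colnames(vals)])
  tibble(state_index = g$state_index, county_index = g$county_index,
         county_id = g$county_id, true_score = score,
         true_rank = rank(score, ties.method = "first"))
}

#' Apply reporting suppression and survey censoring rules
#'
#' Mirrors how restricted vital-statistics and telephone-survey county
#' extracts arrive: count cells based on `suppress_at` or fewer events are
#' suppressed (the count removed, a flag kept), and survey cells are censored
#' when based on fewer than `min_respondents` respondents or when the 95%
#' confidence interval is too wide -- wider than `prevalence_width` on the
#' proportion scale, or wider than `days_rel_width` times the reported mean
#' for the mean-days measures.
#'
#' @param universe A `county_universe`.
#' @param suppress_at Count threshold; cells with events `<= suppress_at`
#'   are suppressed (default 5).
#' @param min_respondents Survey cells with fewer respondents are censored
#'   (default 50).
#' @param prevalence_width Maximum 95% CI width on the prevalence scale
#'   (default 0.20).
#' @param days_rel_width Maximum 95% CI width for mean days, relative to the
#'   reported mean (default 1.0; calibrated so the respondent rule dominates,
#'   as the prevalence-scale rule does at typical prevalences).
#' @return The universe with flags set and censored values removed.
#' @export
apply_censoring <- function(universe, suppress_at = 5, min_respondents = 50,
                            prevalence_width = 0.20, days_rel_width = 1.0) {
  u <- universe
  u$mortality <- u$mortality %>%
    mutate(suppressed = .data$suppressed |
             (!is.na(.data$deaths) & .data$deaths <= suppress_at),
           deaths = ifelse(.data$suppressed, NA_integer_, .data$deaths))
  u$low_birth_weight <- u$low_birth_weight %>%
    mutate(suppressed = .data$suppressed |
             (!is.na(.data$events) & .data$events <= suppress_at),
           events = ifelse(.data$suppressed, NA_integer_, .data$events))
  u$fair_poor_health <- u$fair_poor_health %>%
    mutate(censored = .data$censored |
             .data$n_respondents < min_respondents |
             (!is.na(.data$ci_high) &
                (.data$ci_high - .data$ci_low) > prevalence_width),
           across(all_of(c("prevalence", "ci_low", "ci_high")),
                  ~ ifelse(.data$censored, NA_real_, .x)))
  for (ms in c("poor_physical_days", "poor_mental_days")) {
    u[[ms]] <- u[[ms]] %>%
      mutate(censored = .data$censored |
               .data$n_respondents < min_respondents |
               (!is.na(.data$ci_high) &
                  (.data$ci_high - .data$ci_low) >
                    days_rel_width * .data$mean_days),
             across(all_of(c("mean_days", "ci_low", "ci_high")),
                    ~ ifelse(.data$censored, NA_real_, .x)))
  }
  validate_universe(u)
}

#' Write the truth tables beside a universe
#'
#' Serializes a `truth_record` as plain CSVs (never read by the inference
#' stages).
#' @param truth A `truth_record`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    state_effects = file.path(dir, "truth_state_effects.csv"),
    county_effects = file.path(dir, "truth_county_effects.csv"),
    true_values = file.path(dir, "truth_values.csv"),
    true_composite = file.path(dir, "truth_composite.csv"))
  readr::write_csv(truth$state_effects, paths[["state_effects"]])
  readr::write_csv(truth$county_effects, paths[["county_effects"]])
  readr::write_csv(truth$true_values, paths[["true_values"]])
  readr::write_csv(truth$true_composite, paths[["true_composite"]])
  invisible(paths)
}
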