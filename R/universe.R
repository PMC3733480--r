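#' Assemble a county universe
#'
#' Bundles the per-source county tables into a validated `county_universe`
#' object, the container every modelling stage consumes. Counties are indexed
#' by state `j = 1..J` and county-within-state `k = 1..m_j`; a contiguous
#' `county_id` (1..N, ordered by state then county) is attached internally.
#'
#' @param geography Tibble: `state_index`, `county_index`, `state_label`,
#'   `county_label`, `population` (total resident population).
#' @param demographics Tibble keyed like `geography` with categorical
#'   covariates: `race_black`, `race_asian`, `race_amind`, `race_latino`
#'   (low/medium/high), `urbanization` (large_metro/small_metro/rural),
#'   `pct_female`, `pct_under18`, `pct_over64` (categories 1-4).
#' @param mortality Tibble of age-group death counts: one row per county and
#'   age group with `age_group`, `deaths` (NA when suppressed), `population`
#'   (person-years at risk in the group), `suppressed`.
#' @param low_birth_weight Tibble: `births`, `events` (NA when suppressed),
#'   `suppressed`.
#' @param fair_poor_health Tibble: `prevalence`, `ci_low`, `ci_high`,
#'   `n_respondents`, `censored` (value columns NA when censored).
#' @param poor_physical_days,poor_mental_days Tibbles: `mean_days`, `ci_low`,
#'   `ci_high`, `n_respondents`, `censored`.
#' @param measures Measure configuration, see [measure_config()].
#'
#' @return A `county_universe` object (list of tibbles).
#' @export
county_universe <- function(geography, demographics, mortality,
                            low_birth_weight, fair_poor_health,
                            poor_physical_days, poor_mental_days,
                            measures = measure_config()) {
  u <- structure(list(
    geography = canonical_geography(as_tibble(geography)),
    demographics = canonical_demographics(as_tibble(demographics)),
    mortality = as_tibble(mortality),
    low_birth_weight = as_tibble(low_birth_weight),
    fair_poor_health = as_tibble(fair_poor_health),
    poor_physical_days = as_tibble(poor_physical_days),
    poor_mental_days = as_tibble(poor_mental_days),
    measures = as_tibble(measures)
  ), class = "county_universe")
  validate_universe(u)
}

canonical_geography <- function(g) {
  g %>%
    arrange(.data$state_index, .data$county_index) %>%
    mutate(county_id = row_number())
}

canonical_demographics <- function(d) {
  d %>%
    mutate(across(all_of(c("race_black", "race_asian", "race_amind",
                           "race_latino")),
                  ~ factor(as.character(.x), levels = RACE_LEVELS)),
           urbanization = factor(as.character(.data$urbanization),
                                 levels = URBAN_LEVELS),
           across(all_of(c("pct_female", "pct_under18", "pct_over64")),
                  ~ factor(as.character(.x), levels = QUARTER_LEVELS)))
}

county_key_str <- function(j, k) paste0("(j=", j, ", k=", k, ")")

#' Validate a county universe
#'
#' Checks every structural invariant of the container: unique (state, county)
#' keys, J >= 2, nine age groups per county, deaths <= population, event
#' counts within denominators, confidence limits bracketing their estimates,
#' censored/suppressed cells carrying no values, and the measure weights.
#' Violations raise an error naming the offending county keys.
#'
#' @param universe A `county_universe`.
#' @return The universe, invisibly usable in a pipe (returned visibly).
#' @export
validate_universe <- function(universe) {
  if (!inherits(universe, "county_universe"))
    abort("not a county_universe")
  g <- universe$geography
  if (nrow(g) == 0) abort("universe has an empty county list")
  if (anyDuplicated(g[c("state_index", "county_index")]))
    abort("duplicate (state_index, county_index) keys in geography")
  if (dplyr::n_distinct(g$state_index) < 2)
    abort("universe must contain at least two states (J >= 2)")
  if (any(g$population <= 0))
    abort(paste("nonpositive population for counties:",
                bad_keys(g, g$population <= 0)))
  bad_m <- g %>% group_by(.data$state_index) %>%
    summarise(ok = all(sort(.data$county_index) == seq_len(n()))) %>%
    filter(!.data$ok)
  if (nrow(bad_m) > 0)
    abort(paste("county_index not contiguous 1..m_j in state(s)",
                paste(bad_m$state_index, collapse = ", ")))

  check_keys(universe$demographics, g, "demographics")
  d <- universe$demographics
  for (col in c("race_black", "race_asian", "race_amind", "race_latino",
                "urbanization", "pct_female", "pct_under18", "pct_over64")) {
    if (anyNA(d[[col]]))
      abort(paste0("demographics column ", col,
                   " has values outside its category set for counties: ",
                   bad_keys(d, is.na(d[[col]]))))
  }

  mort <- universe$mortality
  check_keys(distinct(mort, .data$state_index, .data$county_index), g,
             "mortality")
  grp_ok <- mort %>%
    group_by(.data$state_index, .data$county_index) %>%
    summarise(ok = setequal(.data$age_group, AGE_GROUPS), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(grp_ok) > 0)
    abort(paste("mortality must have exactly the 9 age groups per county;",
                "violated for counties:", bad_keys(grp_ok, TRUE)))
  bad <- !mort$suppressed &
    (is.na(mort$deaths) | mort$deaths < 0 | mort$deaths > mort$population)
  if (any(bad))
    abort(paste("mortality deaths missing, negative, or exceeding population",
                "for counties:", bad_keys(mort, bad)))
  bad <- mort$suppressed & !is.na(mort$deaths)
  if (any(bad))
    abort(paste("suppressed mortality cells must not carry death counts:",
                bad_keys(mort, bad)))

  lbw <- universe$low_birth_weight
  check_keys(lbw, g, "low_birth_weight")
  bad <- !lbw$suppressed & (is.na(lbw$events) | lbw$events < 0 |
                              lbw$events > lbw$births)
  if (any(bad))
    abort(paste("low_birth_weight events missing or exceeding births for",
                "counties:", bad_keys(lbw, bad)))
  bad <- lbw$suppressed & !is.na(lbw$events)
  if (any(bad))
    abort(paste("suppressed low-birth-weight cells must not carry events:",
                bad_keys(lbw, bad)))

  fp <- universe$fair_poor_health
  check_keys(fp, g, "fair_poor_health")
  obs <- !fp$censored
  bad <- obs & (is.na(fp$prevalence) | fp$prevalence < 0 | fp$prevalence > 1 |
                  fp$ci_low > fp$prevalence | fp$ci_high < fp$prevalence)
  if (any(bad))
    abort(paste("fair_poor_health prevalence/CI invariant violated for",
                "counties:", bad_keys(fp, bad)))

  for (mm in c("poor_physical_days", "poor_mental_days")) {
    dd <- universe[[mm]]
    check_keys(dd, g, mm)
    obs <- !dd$censored
    bad <- obs & (is.na(dd$mean_days) | dd$mean_days <= 0 |
                    dd$mean_days > 30 |
                    dd$ci_low > dd$mean_days | dd$ci_high < dd$mean_days)
    if (any(bad))
      abort(paste0(mm, " mean/CI invariant violated for counties: ",
                   bad_keys(dd, bad)))
  }

  validate_measure_config(universe$measures)
  universe
}

bad_keys <- function(df, flag) {
  ks <- df[which(flag), , drop = FALSE]
  ks <- utils::head(unique(county_key_str(ks$state_index, ks$county_index)), 10)
  paste(ks, collapse = ", ")
}

check_keys <- function(df, g, what) {
  miss <- dplyr::anti_join(g, df, by = c("state_index", "county_index"))
  extra <- dplyr::anti_join(df, g, by = c("state_index", "county_index"))
  if (nrow(miss) > 0)
    abort(paste0(what, " missing counties: ", bad_keys(miss, TRUE)))
  if (nrow(extra) > 0)
    abort(paste0(what, " has counties absent from geography: ",
                 bad_keys(extra, TRUE)))
  invisible(df)
}

#' @export
print.county_universe <- function(x, ...) {
  g <- x$geography
  cat("<county_universe> ", nrow(g), " counties in ",
      dplyr::n_distinct(g$state_index), " states\n", sep = "")
  cat("  population: median ", round(median(g$population)),
      ", range [", min(g$population), ", ", max(g$population), "]\n", sep = "")
  cens <- c(
    mortality = mean(x$mortality$suppressed),
    low_birth_weight = mean(x$low_birth_weight$suppressed),
    fair_poor_health = mean(x$fair_poor_health$censored),
    poor_physical_days = mean(x$poor_physical_days$censored),
    poor_mental_days = mean(x$poor_mental_days$censored))
  cat("  suppressed/censored fraction by table:\n")
  for (nm in names(cens))
    cat(sprintf("    %-20s %.3f\n", nm, cens[[nm]]))
  invisible(x)
}

# ---- delimited-text serialization -------------------------------------------

universe_files <- c("geography", "demographics", "mortality",
                    "low_birth_weight", "fair_poor_health",
                    "poor_physical_days", "poor_mental_days", "measures")

#' Write a county universe as CSV files
#'
#' One CSV per source table (geography, demographics, one per measure, plus
#' the measure configuration), keyed by `(state_label, county_label)` with
#' 1-based state/county indices, UTF-8, header row, fixed column order.
#' Censored or suppressed cells serialize with empty value fields and an
#' explicit flag column -- never a sentinel zero.
#'
#' @param universe A validated `county_universe`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_universe <- function(universe, dir) {
  validate_universe(universe)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(universe_files, ".csv")),
                    universe_files)
  key <- universe$geography %>%
    select("state_index", "county_index", "state_label", "county_label")
  put <- function(tbl, path, drop_key = TRUE) {
    if (all(c("state_index", "county_index") %in% names(tbl)) && drop_key) {
      tbl <- key %>%
        inner_join(tbl, by = c("state_index", "county_index")) %>%
        select(-"state_index", -"county_index")
    }
    readr::write_csv(tbl, path, na = "")
  }
  readr::write_csv(select(universe$geography, -"county_id"),
                   paths[["geography"]], na = "")
  put(universe$demographics, paths[["demographics"]])
  put(universe$mortality, paths[["mortality"]])
  put(universe$low_birth_weight, paths[["low_birth_weight"]])
  put(universe$fair_poor_health, paths[["fair_poor_health"]])
  put(universe$poor_physical_days, paths[["poor_physical_days"]])
  put(universe$poor_mental_days, paths[["poor_mental_days"]])
  readr::write_csv(universe$measures, paths[["measures"]], na = "")
  invisible(paths)
}

#' Read a county universe from CSV files
#'
#' Inverse of [write_universe()]: `read_universe(write_universe(u)) == u`.
#' Malformed rows raise an error naming the file and problem; invariant
#' violations raise validation errors listing county keys.
#'
#' @param dir Directory holding the files written by [write_universe()].
#' @return A validated `county_universe`.
#' @export
read_universe <- function(dir) {
  paths <- setNames(file.path(dir, paste0(universe_files, ".csv")),
                    universe_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    abort(paste("missing universe files:", paste(missing, collapse = ", ")))

  grab <- function(name, col_types) {
    # parsing problems are surfaced as errors below, not readr warnings
    tb <- suppressWarnings(readr::read_csv(paths[[name]],
                                           col_types = col_types,
                                           progress = FALSE))
    probs <- readr::problems(tb)
    if (nrow(probs) > 0)
      abort(paste0("malformed row in ", paths[[name]], ": line ",
                   probs$row[1], ", column ", probs$col[1], " (",
                   probs$expected[1], ")"))
    tb
  }

  geography <- grab("geography", readr::cols(
    state_index = readr::col_integer(), county_index = readr::col_integer(),
    state_label = readr::col_character(),
    county_label = readr::col_character(),
    population = readr::col_double()))
  key <- geography %>%
    select("state_index", "county_index", "state_label", "county_label")
  rekey <- function(tbl, name) {
    out <- left_join(tbl, key, by = c("state_label", "county_label"))
    if (anyNA(out$state_index))
      abort(paste0(name, ".csv has (state_label, county_label) pairs absent ",
                   "from geography.csv"))
    out %>% select(-"state_label", -"county_label") %>%
      select("state_index", "county_index", dplyr::everything())
  }

  demographics <- rekey(grab("demographics", readr::cols(
    .default = readr::col_character())), "demographics")
  mortality <- rekey(grab("mortality", readr::cols(
    state_label = readr::col_character(),
    county_label = readr::col_character(),
    age_group = readr::col_character(),
    deaths = readr::col_integer(), population = readr::col_double(),
    suppressed = readr::col_logical())), "mortality")
  lbw <- rekey(grab("low_birth_weight", readr::cols(
    state_label = readr::col_character(),
    county_label = readr::col_character(),
    births = readr::col_double(), events = readr::col_integer(),
    suppressed = readr::col_logical())), "low_birth_weight")
  fph <- rekey(grab("fair_poor_health", readr::cols(
    state_label = readr::col_character(),
    county_label = readr::col_character(),
    prevalence = readr::col_double(), ci_low = readr::col_double(),
    ci_high = readr::col_double(), n_respondents = readr::col_integer(),
    censored = readr::col_logical())), "fair_poor_health")
  days_types <- readr::cols(
    state_label = readr::col_character(),
    county_label = readr::col_character(),
    mean_days = readr::col_double(), ci_low = readr::col_double(),
    ci_high = readr::col_double(), n_respondents = readr::col_integer(),
    censored = readr::col_logical())
  ppd <- rekey(grab("poor_physical_days", days_types), "poor_physical_days")
  pmd <- rekey(grab("poor_mental_days", days_types), "poor_mental_days")
  measures <- grab("measures", readr::cols(
    measure = readr::col_character(), family = readr::col_character(),
    weight = readr::col_double()))

  county_universe(geography = geography,
                  demographics = demographics %>%
                    mutate(across(c("state_index", "county_index"),
                                  as.integer)),
                  mortality = mortality,
                  low_birth_weight = lbw,
                  fair_poor_health = fph,
                  poor_physical_days = ppd,
                  poor_mental_days = pmd,
                  measures = measures)
}

# County-level table for one measure with county_id attached.
measure_table <- function(universe, measure) {
  tbl <- switch(measure,
                premature_mortality = universe$mortality,
                low_birth_weight = universe$low_birth_weight,
                fair_poor_health = universe$fair_poor_health,
                poor_physical_days = universe$poor_physical_days,
                poor_mental_days = universe$poor_mental_days,
                abort(paste("unknown measure:", measure)))
  left_join(tbl,
            select(universe$geography, "state_index", "county_index",
                   "county_id"),
            by = c("state_index", "county_index"))
}

n_counties <- function(universe) nrow(universe$geography)
n_states <- function(universe) dplyr::n_distinct(universe$geography$state_index)
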