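#' Build the fixed-effect design for a county universe
#'
#' Model 1 is intercept-only. Model 2 adds the categorical demographic
#' covariates with reference levels: race proportions (low reference),
#' urbanization (large_metro reference), and the percent-female, under-18 and
#' over-64 categories (category 1 reference) -- with every category observed
#' this gives 1 + 4*2 + 2 + 3*3 = 20 fixed-effect columns. Categories listed
#' in the covariate scheme but absent from the data are dropped from the
#' design with a warning naming them; a covariate whose observed values
#' collapse to a single level is dropped entirely with a warning, so
#' degenerate universes (e.g. all-rural) still yield a full-rank design.
#'
#' @param universe A `county_universe`.
#' @param model_form `"model1"` or `"model2"`.
#' @return A list: `model_form`, `terms` (covariate columns kept), `cov_data`
#'   (county-level covariate tibble, one row per `county_id`), `X` (the
#'   county-level model matrix including the intercept), `dropped`
#'   (character vector describing any dropped categories/covariates).
#' @export
build_design <- function(universe, model_form = c("model1", "model2")) {
  model_form <- match.arg(model_form)
  g <- universe$geography
  d <- universe$demographics %>%
    left_join(select(g, "state_index", "county_index", "county_id"),
              by = c("state_index", "county_index")) %>%
    arrange(.data$county_id)

  dropped <- character()
  terms <- character()
  if (model_form == "model2") {
    cov_cols <- c("race_black", "race_asian", "race_amind", "race_latino",
                  "urbanization", "pct_female", "pct_under18", "pct_over64")
    for (col in cov_cols) {
      f <- d[[col]]
      absent <- setdiff(levels(f), unique(as.character(f)))
      if (length(absent) > 0) {
        f <- droplevels(f)
        d[[col]] <- f
        if (nlevels(f) < 2) {
          dropped <- c(dropped, paste0(
            "covariate ", col, " collapsed to a single level ('",
            levels(f), "'); dropped from the design"))
          next
        }
        dropped <- c(dropped, paste0(
          "covariate ", col, ": category(ies) ",
          paste(absent, collapse = ", "),
          " absent from the data; corresponding dummies dropped"))
      }
      terms <- c(terms, col)
    }
    if (length(dropped) > 0)
      warn(paste(dropped, collapse = "\n"))
  }

  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), data = d)
  list(model_form = model_form, terms = terms,
       cov_data = select(d, "county_id", all_of(terms)),
       X = X, dropped = dropped)
}
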