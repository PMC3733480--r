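#' Composite health-outcome scores from per-measure posterior samples
#'
#' Within each posterior sample, each measure's county values are
#' standardized to national z scores (mean 0, SD 1 across all N counties),
#' weighted by the composite scheme (premature mortality 0.50, fair/poor
#' health 0.10, poor physical days 0.10, poor mental days 0.10, low birth
#' weight 0.20), and summed. All five measures are adverse, so a higher
#' composite score means worse health.
#'
#' @param samples Named list of `posterior_samples`, one per measure, each
#'   with an `S x N` values matrix (mortality already converted to YPLL-75,
#'   see [ypll_from_samples()]), aligned on counties and samples.
#' @param weights A measure configuration tibble ([measure_config()]).
#' @return An `S x N` matrix of composite scores with the county table
#'   attached as attribute `counties`.
#' @export
composite_scores <- function(samples, weights = measure_config()) {
  validate_measure_config(weights)
  if (!setequal(names(samples), weights$measure))
    abort("samples must be a named list covering exactly the five measures")
  dims <- map(samples, ~ dim(.x$values))
  if (length(unique(map(dims, identity))) != 1 ||
      any(map_int(dims, length) != 2))
    abort("per-measure sample matrices misaligned (need same S x N)")
  S <- dims[[1]][1]
  N <- dims[[1]][2]
  score <- matrix(0, S, N)
  for (ms in weights$measure) {
    x <- samples[[ms]]$values
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (N - 1))
    if (any(s == 0))
      abort(paste("zero within-sample SD for", ms, "(degenerate universe)"))
    w <- weights$weight[weights$measure == ms]
    score <- score + w * (x - mu) / s
  }
  attr(score, "counties") <- samples[[1]]$counties
  score
}

#' Per-sample county ranks
#'
#' Ranks the composite scores within each posterior sample: rank 1 is the
#' lowest (healthiest) score; exact ties are broken by county order, so the
#' earlier-indexed county takes the lower rank.
#'
#' @param scores `S x N` score matrix from [composite_scores()].
#' @return `S x N` integer matrix of ranks.
#' @export
rank_samples <- function(scores) {
  if (!all(is.finite(scores))) abort("scores must be finite")
  r <- t(apply(scores, 1, rank, ties.method = "first"))
  storage.mode(r) <- "integer"
  attr(r, "counties") <- attr(scores, "counties")
  r
}

rank_quartile <- function(r, N) {
  cuts <- c(ceiling(N / 4), ceiling(N / 2), ceiling(3 * N / 4))
  1L + (r > cuts[1]) + (r > cuts[2]) + (r > cuts[3])
}

#' Summarize posterior rank distributions
#'
#' For each county: the point rank (the rank of its posterior mean rank,
#' ties by county order -- point ranks always form a permutation of 1..N),
#' the central credible interval of its posterior rank distribution (order
#' statistic quantiles with outward rounding, so empirical coverage errs
#' conservative), the credible-interval width in ranks and percentile ranks
#' (`width * 100 / N`), the national quartile assigned from the point rank
#' (cut points `ceiling(N/4)`, `ceiling(N/2)`, `ceiling(3N/4)`), the
#' posterior probability of falling in each quartile, and the certainty flag
#' (probability of the assigned quartile at or above `certainty_threshold`).
#'
#' @param rank_array `S x N` rank matrix from [rank_samples()].
#' @param level Credible level (default 0.90).
#' @param certainty_threshold High-certainty cutoff on the assigned-quartile
#'   probability (default 0.80).
#' @return A `rank_summary` tibble, one row per county.
#' @export
summarize_ranks <- function(rank_array, level = 0.90,
                            certainty_threshold = 0.80) {
  S <- nrow(rank_array)
  N <- ncol(rank_array)
  if (S < 100) abort("at least 100 posterior samples required")
  counties <- attr(rank_array, "counties") %||%
    tibble(state_index = NA_integer_, county_index = NA_integer_,
           county_id = seq_len(N))

  mean_rank <- colMeans(rank_array)
  point_rank <- rank(mean_rank, ties.method = "first")
  i_lo <- max(1L, floor((1 - level) / 2 * S))
  i_hi <- min(S, ceiling((1 + level) / 2 * S))
  sorted <- apply(rank_array, 2, sort)
  ci_low <- sorted[i_lo, ]
  ci_high <- sorted[i_hi, ]

  q_sample <- rank_quartile(rank_array, N)  # S x N
  probs <- vapply(1:4, function(q) colMeans(q_sample == q), numeric(N))
  assigned <- rank_quartile(point_rank, N)
  p_assigned <- probs[cbind(seq_len(N), assigned)]

  out <- tibble(
    state_index = counties$state_index,
    county_index = counties$county_index,
    county_id = counties$county_id,
    mean_rank = mean_rank,
    point_rank = as.integer(point_rank),
    ci_low = as.integer(ci_low),
    ci_high = as.integer(ci_high),
    ci_width = as.integer(ci_high - ci_low),
    percentile_ci_width = (ci_high - ci_low) * 100 / N,
    assigned_quartile = as.integer(assigned),
    q1_prob = probs[, 1], q2_prob = probs[, 2],
    q3_prob = probs[, 3], q4_prob = probs[, 4],
    assigned_quartile_prob = p_assigned,
    high_certainty = p_assigned >= certainty_threshold)
  structure(out, class = c("rank_summary", class(out)),
            level = level, certainty_threshold = certainty_threshold,
            S = S, N = N)
}

#' Compare rank precision between two model forms
#'
#' The same summaries used to report whether demographic covariates improve
#' rank precision: mean credible-interval width in ranks and in percentile
#' ranks under each model, the difference, and the count and fraction of
#' counties ranking in their assigned quartile with high certainty.
#'
#' @param summary1,summary2 `rank_summary` tibbles for the same universe
#'   (e.g. model 1 and model 2).
#' @param labels Length-2 labels for the two summaries.
#' @return A `rank_model_comparison`: a tibble with one row per model plus
#'   difference attributes (`delta_*`, summary2 minus summary1).
#' @export
compare_models <- function(summary1, summary2,
                           labels = c("model1", "model2")) {
  key <- c("state_index", "county_index")
  if (nrow(summary1) != nrow(summary2) ||
      !identical(summary1[key], summary2[key]))
    abort("summaries cover different county sets")
  one <- function(s, lab) {
    tibble(model = lab,
           n_counties = nrow(s),
           mean_ci_width_ranks = mean(s$ci_width),
           mean_ci_width_percentile = mean(s$percentile_ci_width),
           n_high_certainty = sum(s$high_certainty),
           frac_high_certainty = mean(s$high_certainty))
  }
  out <- bind_rows(one(summary1, labels[1]), one(summary2, labels[2]))
  structure(out, class = c("rank_model_comparison", class(out)),
            delta_mean_ci_width_ranks =
              out$mean_ci_width_ranks[2] - out$mean_ci_width_ranks[1],
            delta_mean_ci_width_percentile =
              out$mean_ci_width_percentile[2] - out$mean_ci_width_percentile[1],
            delta_frac_high_certainty =
              out$frac_high_certainty[2] - out$frac_high_certainty[1])
}

#' @export
print.rank_model_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf(
    "\nDifference (%s - %s): %+.1f ranks, %+.2f percentile ranks, %+.1f%% high-certainty\n",
    x$model[2], x$model[1],
    attr(x, "delta_mean_ci_width_ranks"),
    attr(x, "delta_mean_ci_width_percentile"),
    100 * attr(x, "delta_frac_high_certainty")))
  invisible(x)
}

#' Rank counties end to end from a fitted universe
#'
#' Convenience wrapper: posterior samples for all five measures (YPLL-75 for
#' mortality), composite scores, per-sample ranks, and the rank summary.
#'
#' @param fits Named list from [fit_all_measures()].
#' @param universe The universe the fits came from.
#' @param S Posterior sample count.
#' @param seed Master seed; per-measure draw seeds are derived from it.
#' @param level,certainty_threshold Passed to [summarize_ranks()].
#' @return A `rank_summary` tibble.
#' @export
rank_universe <- function(fits, universe, S = 1000, seed,
                          level = 0.90, certainty_threshold = 0.80) {
  samples <- imap(fits, function(f, ms) {
    posterior_measure_samples(
      f, universe, S = S,
      seed = seed + match(ms, MEASURE_NAMES))
  })
  scores <- composite_scores(samples, universe$measures)
  summarize_ranks(rank_samples(scores), level = level,
                  certainty_threshold = certainty_threshold)
}
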