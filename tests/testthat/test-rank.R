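five_measure_samples <- function(vals_fun, S = 120, N = 10) {
  cfg <- measure_config()
  out <- purrr::map(seq_len(5), function(i) {
    fam <- cfg$family[i]
    make_samples(vals_fun(i), measure = cfg$measure[i],
                 family = if (fam == "poisson") "binomial" else fam)
  })
  setNames(out, cfg$measure)
}

test_that("composite scores implement the weighted z-score scheme", {
  S <- 120; N <- 5
  # county values 1..5 within every sample and measure: z = (x - 3)/sd
  base <- matrix(rep(1:5, each = S), S, N)
  samples <- five_measure_samples(function(i) base)
  sc <- composite_scores(samples)
  z <- (1:5 - 3) / sd(1:5)
  expect_equal(sc[1, ], z, ignore_attr = TRUE)      # weights sum to 1
  expect_equal(sc[S, ], z, ignore_attr = TRUE)
  # a county at every measure's mean scores exactly 0
  expect_equal(sc[, 3], rep(0, S))
  # a county exactly 1 SD worse on every measure scores the weight total, 1:
  # v has mean 0 and SD 1, so county 4 sits exactly 1 SD above the mean
  v <- c(-1, -1, 0, 1, 1)
  samples2 <- five_measure_samples(function(i) matrix(rep(v, each = S), S, N))
  sc2 <- composite_scores(samples2)
  expect_equal(sc2[1, 4], 0.5 + 0.1 + 0.1 + 0.1 + 0.2, tolerance = 1e-12)
  expect_equal(sc2[1, 4], 1)
})

test_that("composite scores are invariant to affine rescaling of a measure", {
  set.seed(7)
  S <- 150; N <- 12
  vals <- purrr::map(1:5, ~ matrix(rlnorm(S * N), S, N))
  samples <- five_measure_samples(function(i) vals[[i]])
  sc1 <- composite_scores(samples)
  samples$premature_mortality$values <- 2 * samples$premature_mortality$values
  sc2 <- composite_scores(samples)
  expect_equal(sc1, sc2, tolerance = 1e-12)
  samples$low_birth_weight$values <- samples$low_birth_weight$values + 0.17
  expect_equal(composite_scores(samples), sc1, tolerance = 1e-10)
})

test_that("a constant measure across counties is a degenerate universe", {
  S <- 120; N <- 6
  samples <- five_measure_samples(function(i)
    if (i == 2) matrix(0.3, S, N) else matrix(runif(S * N), S, N))
  expect_error(composite_scores(samples), "zero within-sample SD")
})

test_that("per-sample ranks follow the sort order with index tie-breaking", {
  sc <- rbind(c(-1, 0, 1), c(1, 0, -1), c(0.5, 0.5, -2))
  r <- rank_samples(sc)
  expect_identical(r[1, ], c(1L, 2L, 3L))
  expect_identical(r[2, ], c(3L, 2L, 1L))
  expect_identical(r[3, ], c(2L, 3L, 1L))  # tie: earlier county ranks lower

  set.seed(31)
  for (i in 1:100) {
    x <- matrix(rnorm(40), 1)
    expect_identical(rank_samples(x)[1, ], rank(x[1, ], ties.method = "first"))
    o <- order(x[1, ])  # brute-force sort oracle
    expect_identical(rank_samples(x)[1, o], seq_len(40))
  }
  expect_error(rank_samples(matrix(c(1, Inf), 1)), "finite")
})

test_that("rank summaries are exact in the no-uncertainty limit", {
  S <- 200; N <- 8
  sc <- matrix(rep(seq_len(N), each = S), S, N)
  attr(sc, "counties") <- tibble::tibble(state_index = 1L,
                                         county_index = seq_len(N),
                                         county_id = seq_len(N))
  summ <- summarize_ranks(rank_samples(sc))
  expect_identical(summ$point_rank, seq_len(N))
  expect_identical(summ$ci_low, summ$point_rank)
  expect_identical(summ$ci_high, summ$point_rank)
  expect_equal(summ$ci_width, rep(0L, N))
  expect_equal(summ$assigned_quartile_prob, rep(1, N))
  probs <- as.matrix(summ[c("q1_prob", "q2_prob", "q3_prob", "q4_prob")])
  expect_equal(rowSums(probs), rep(1, N))
  expect_identical(summ$assigned_quartile, rep(1:4, each = 2))
})

test_that("rank summaries behave on stochastic rank distributions", {
  fx <- fixture_fit_universe()
  samples <- fixture_samples()
  sc <- composite_scores(samples, fx$universe$measures)
  r <- rank_samples(sc)
  s90 <- summarize_ranks(r, level = 0.90)
  N <- ncol(r)
  expect_setequal(s90$point_rank, seq_len(N))  # permutation of 1..N
  expect_true(all(s90$ci_low <= s90$point_rank &
                    s90$point_rank <= s90$ci_high))
  probs <- as.matrix(s90[c("q1_prob", "q2_prob", "q3_prob", "q4_prob")])
  expect_equal(rowSums(probs), rep(1, N), tolerance = 1e-9)
  expect_identical(s90$high_certainty, s90$assigned_quartile_prob >= 0.8)
  expect_equal(s90$percentile_ci_width, s90$ci_width * 100 / N)

  # CI monotone in level: the 80% interval nests inside the 90% interval
  s80 <- summarize_ranks(r, level = 0.80)
  expect_true(all(s80$ci_low >= s90$ci_low))
  expect_true(all(s80$ci_high <= s90$ci_high))
})

test_that("model comparison reports widths, certainty shares, and differences", {
  fx <- fixture_fit_universe()
  samples <- fixture_samples()
  sc <- composite_scores(samples, fx$universe$measures)
  summ <- summarize_ranks(rank_samples(sc))
  cmp <- compare_models(summ, summ)
  expect_equal(attr(cmp, "delta_mean_ci_width_ranks"), 0)
  expect_equal(attr(cmp, "delta_mean_ci_width_percentile"), 0)
  expect_equal(attr(cmp, "delta_frac_high_certainty"), 0)
  expect_equal(cmp$mean_ci_width_percentile,
               cmp$mean_ci_width_ranks * 100 / nrow(summ))
  other <- summ[rev(seq_len(nrow(summ))), ]
  expect_error(compare_models(summ, other), "different county sets")
})
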