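---
title: "Quantifying rank uncertainty in composite county health measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rank uncertainty in composite county health measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countyrank)
```

## The problem

County health rankings order every county by a composite of noisy
health-outcome measures. A rank is a far less stable quantity than the
estimates beneath it: small differences in underlying rates reshuffle the
league table, and counties with small populations or mid-table composite
scores can plausibly occupy hundreds of different positions. `countyrank`
quantifies that instability. It fits hierarchical models to five
health-outcome measures, draws joint posterior samples of every county's
values, rebuilds the composite score and the national ranking inside each
posterior sample, and reports for every county a point rank, a central 90%
credible interval for its rank, and the posterior probability that it
belongs in its assigned national quartile.

## The model

Each measure is modeled with nested random effects for state `j = 1..J` and
county `k = 1..m_j` within state:

\[
\mathrm{link}(\rho_{jk}) = x_{jk}'\beta + e_j + e_{jk}, \qquad
e_j \sim N(0, \sigma_j^2), \quad e_{jk} \sim N(0, \sigma_{jk}^2).
\]

Model 1 uses an intercept only; model 2 adds categorical demographic
covariates (four race/ethnicity proportions coded low `< 6%` / medium
`6–39%` / high `>= 40%`; urbanization large-metro / small-metro / rural;
percent female, under 18 and over 64 in four categories each), dummy-coded
against reference levels (low, large_metro, category 1), giving 20
fixed-effect columns when every category is observed. The covariates inform
the estimates; they are not used to adjust ranks.

The five measures use three observation families:

* **Premature mortality (Poisson, log link).** Death counts for nine age
  groups (`<1`, `1–4`, then ten-year bands to `65–74`) with person-years
  offsets. The intercept expands to nine age-group intercepts; one county
  random effect is shared by all nine groups. This is the minimal structure
  consistent with a single county effect per measure; fitting nine separate
  group-level models would be the main alternative and would require its own
  cross-group combination rule.
* **Low birth weight and fair/poor health (binomial, logit link).** Birth
  counts are used directly. Survey prevalence arrives as an estimate with a
  95% CI; the implied standard error `SE = (ci_high − ci_low)/(2 × 1.959964)`
  yields an effective denominator `n_eff = p(1−p)/SE^2` (rounded, floored at
  1) and numerator `round(p × n_eff)`. The logit link is the standard GLMM
  choice; the mortality specification is the only one whose link is forced
  by the modeling tradition being followed.
* **Poor physical and mental health days (log-normal).** Reported county
  means are log-transformed to control overdispersion, with known sampling
  variances from the delta method,
  `Var(log X̄) ≈ ((ci_high − ci_low)/(2z))^2 / X̄^2`, used as inverse-variance
  weights. With one observation per county and known sampling variances this
  is exactly a three-level meta-analytic model, fitted by ML with
  `metafor::rma.mv`.

Poisson and binomial models are fitted by Laplace-approximate maximum
likelihood with `lme4::glmer` (nested `(1|state) + (1|county)` intercepts).
The package carries its own penalized-Newton Laplace machinery
(`laplace_loglik()`), used three ways: to cross-check the fitted likelihood
against adaptive numerical integration on small problems, to verify that
the optimum dominates the generating truth on synthetic data, and as a
fallback maximum-likelihood fitter for degenerate configurations (an
exactly constant response stalls `glmer`'s PIRLS iterations regardless of
tolerance).

Suppressed and censored cells are simply excluded from the likelihood.
Counties without data stay in the universe: their random effects have
posterior mode 0 and conditional variance `sigma_county^2`, so they are
ranked from their prior predictive distribution — imputation happens
through the model, never by substituting a point value.

## Empirical Bayes conditioning and posterior samples

Variance parameters are estimated once and then held fixed — the empirical
Bayes convention. Conditioning on `(sigma_j, sigma_jk)`, the joint posterior
of the stacked vector `(beta, e_1..e_J, e_11..e_Jm)` is approximated as
multivariate normal: the mode maximizes the joint log-posterior (flat prior
on `beta`), and the covariance is the inverse negative Hessian at the mode.
Because variance-parameter uncertainty is not propagated, the resulting
rank intervals are, if anything, optimistic; this is inherent to the
empirical Bayes design, not a computational shortcut.

`draw_samples()` draws `S` joint normal samples (default 1000; a seed is
mandatory, and every stage seed is derived from the run seed) and pushes
them through the linear predictor and inverse link to natural-scale county
values. For mortality, the nine age-group rate samples are combined into
YPLL-75 — years of potential life lost before 75 per 100,000 population —
weighting each death by `75 − age at death` with age taken at the group
midpoint (0.5, 3, 10, ..., 70; configurable). The measure is crude, not
age-standardized: only the 75-minus-age weighting is part of the published
construction being mirrored, and the midpoint convention is ours, so it is
exposed as a parameter rather than hard-coded.

## Composite scores, ranks, and certainty

Within each posterior sample, each measure's county values are standardized
to national z-scores (mean 0, SD 1 across all counties), weighted 0.50
(premature mortality), 0.10, 0.10, 0.10 (survey measures), 0.20 (low birth
weight), and summed; all measures are adverse, so higher = worse, and rank
1 = healthiest. Standardization is recomputed inside every posterior sample
rather than frozen at point estimates — the alternative (fixed national
moments) changes results only marginally but breaks the interpretation of
each sample as a complete replicate ranking.

Per county, the point rank is the rank of the posterior mean rank (point
ranks therefore always form a permutation of 1..N); ties anywhere are broken
by county order, deterministically. The credible interval takes order
statistics of the county's sampled ranks with outward index rounding
(`floor` for the lower, `ceiling` for the upper cut), so empirical coverage
errs conservative — the quantile estimator is otherwise unstated in the
tradition this follows, and for an uncertainty product conservative is the
safer default. Quartiles are assigned from the point rank against cut
points `ceiling(N/4)`, `ceiling(N/2)`, `ceiling(3N/4)`; quartile
probabilities come from the sampled ranks, and a county is flagged
high-certainty when the probability of its assigned quartile is at least
0.80. Ranking is national throughout: state-level clustering makes in-state
intervals both wide and model-inconsistent, so no in-state product is
offered.

## Posterior predictive checks

`ppc_check()` simulates replicate datasets from the posterior samples and
the reported denominators — Poisson deaths per age group (recombined into
YPLL), binomial events over reported or effective denominators, normal
replicates of log mean-days with the county sampling SD — for counties
contributing observed data. The discrepancy statistic is the interquartile
range of the measure across counties (linear-interpolation quantiles),
computed on the natural measure scale; the posterior predictive p-value is
two-sided, `2 × min(Pr(IQR_rep ≥ IQR_obs), Pr(IQR_rep ≤ IQR_obs))`, with
`ppp ≥ 0.05` flagged adequate. The mortality check runs on YPLL rates
across fully observed counties; per-age-group checks are possible by
passing the group-level samples directly. The IQR across counties is the
one distribution observable at this aggregation level; alternative
discrepancies (mean, tail counts) are easy to compute from
`replicate_datasets()` but are not part of the contract.

## The synthetic universe generator

Real inputs of this kind are restricted extracts; the generator is the
package's stand-in with known truth, and its defaults are fixed study
conditions rather than tuning knobs:

* **Populations** are log-normal (median 75,000 person-years — roughly
  25,000 residents over a three-year reporting window — `sdlog` 1.2,
  floor 750), so genuinely small counties exist; they drive all censoring
  and shrinkage phenomena.
* **Mortality** uses a realistic age curve (annual rates from 0.00015 in
  ages 5–14 to 0.0215 in 65–74) with the shared county effect
  (`sigma_state = 0.10`, `sigma_county = 0.25` on the log scale), and an
  optional per-cell overdispersion SD used only to create deliberately
  misspecified universes for PPC power checks.
* **Survey measures** use a respondent rate of 0.004 per person-year
  (median county ≈ 300 respondents), baseline prevalence 15% for fair/poor
  health, and mean poor physical/mental health days 3.7/3.4 with
  person-level coefficient of variation 1.9 feeding the reported means and
  CIs. Reported values carry six decimals, as fixed-precision extracts do.
* **Low birth weight** uses a births rate of 0.013 per person-year and
  baseline prevalence 8%.
* **Censoring** mirrors the reporting rules: count cells with 5 or fewer
  events suppressed; survey cells censored below 50 respondents or when the
  95% CI is too wide — more than 20 points on the prevalence scale, or more
  than 1.0 times the reported mean for the day measures. The day-measure
  threshold deserves a note: a literal 0.2 relative width with a realistic
  person-level CV would censor every county below roughly 1,400
  respondents, i.e. the large majority, far outside the few-percent
  missingness observed in real county tables. The prevalence rule at
  typical prevalence (~15%) bites at almost exactly 50 respondents, so the
  day-measure analogue is calibrated the same way (1.0 relative width bites
  near 55); both thresholds are arguments to `apply_censoring()`. With the
  default populations, per-measure county-level missingness lands in the
  few-percent range, matching what national county tables exhibit.
* **Model-2 universes** pass every covariate's effect (adverse-positive,
  e.g. +0.20 for a high Black population share, −0.10 for high Asian share,
  +0.12 for rural) into all five linear predictors, scaled by
  `covariate_scale`.

What the generator deliberately does not emulate: real geography or FIPS
codes, spatial correlation between neighboring states (the model has none),
survey design effects beyond the reported CIs, and informative (small
county) suppression bias correction — suppressed cells are missing
not-at-random in both the real reporting rules and the generator, and the
models treat them as ignorable given the random effects, exactly as the
estimation tradition does. Passing calibration on these universes therefore
shows the machinery is correct under its own assumptions, not that real
rankings meet nominal coverage.

## Numerical choices and degenerate inputs

* `z* = 1.959964` wherever a 95% CI is converted to a standard error.
* Newton iterations for joint modes stop at gradient `1e-9 (1 + |objective|)`;
  glmer runs `bobyqa` with derivative checks off; a PIRLS stall triggers one
  retry at relaxed tolerance and then the internal Laplace ML fitter.
* Effective counts are rounded to integers (floored at 1) because the
  binomial likelihood needs integers; prevalence exactly 0 or 1 makes the
  implied SE degenerate, and such cells are excluded with a warning.
* Covariate categories absent from the data are dropped from the design
  with a warning naming them (a covariate collapsing to one level is
  dropped entirely), so degenerate universes fit rather than crash;
  coefficients for dropped categories are simply unavailable.
* Posterior covariance matrices are symmetrized and eigendecomposed; small
  negative eigenvalues are clamped at zero, genuinely indefinite matrices
  are refused.
* A universe in which some measure is constant across counties within a
  sample has no z-scores and is refused as degenerate.

## Problem sizes used in the tests

The calibration suite uses universes of 10 states x 20 counties with
S = 500 posterior samples (50 replicates for coverage and PPC uniformity),
parameter recovery runs at 20 states x 50 counties over 20 seeds, and the
m-sweep uses 10/25/50 counties per state. These sizes are large enough for
the Monte-Carlo error of each check to sit well inside its acceptance band
while keeping a full suite run to minutes on one core.

## Known limitations

* Variance-parameter uncertainty is not propagated; rank intervals are
  anti-conservative to that extent (partly offset by the conservative
  quantile convention).
* With few states (J near 10), `sigma_j` is estimated from few replicates
  and its estimation error is the dominant parameter-recovery error term.
* The YPLL construction is crude (not age-standardized) and uses midpoint
  age-at-death weighting within groups.
* Suppression is informative in reality and in the generator, but the
  likelihood treats missing cells as ignorable — the same approximation the
  published methodology makes.
* No spatial structure beyond state membership; no longitudinal pooling;
  no multivariate modeling of the five measures jointly.
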