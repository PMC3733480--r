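#' @importFrom generics tidy glance
NULL

#' Tidy a measure fit
#'
#' @param x A `measure_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms and estimates.
#' @method tidy measure_fit
#' @export
tidy.measure_fit <- function(x, ...) {
  x$beta
}

#' One-row summary of a measure fit
#'
#' @param x A `measure_fit`.
#' @param ... Unused.
#' @return One-row tibble: measure, family, model form, variance components,
#'   log-likelihood, convergence flag, observation count.
#' @method glance measure_fit
#' @export
glance.measure_fit <- function(x, ...) {
  tibble(measure = x$measure, family = x$family, model_form = x$model_form,
         sigma_state_hat = x$sigma_state_hat,
         sigma_county_hat = x$sigma_county_hat,
         loglik = x$loglik, converged = x$converged, n_obs = x$n_obs,
         n_counties = x$N, n_states = x$J)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
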