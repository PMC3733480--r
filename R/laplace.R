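# Shared penalized-likelihood machinery: the joint log-posterior of fixed
# effects and random effects given fixed variance parameters is maximized by
# Newton iterations, and its negative Hessian at the mode supplies both the
# Laplace-approximate marginal likelihood and the multivariate normal
# approximation used for empirical Bayes posterior sampling.

fam_loglik <- function(family, y, eta, size = NULL, v = NULL) {
  switch(family,
         poisson = sum(dpois(y, exp(eta), log = TRUE)),
         binomial = sum(dbinom(y, size, plogis(eta), log = TRUE)),
         lognormal = sum(dnorm(y, eta, sqrt(v), log = TRUE)))
}

# score and curvature of the log-likelihood wrt the linear predictor
fam_deriv <- function(family, y, eta, size = NULL, v = NULL) {
  switch(family,
         poisson = {
           mu <- exp(eta)
           list(g = y - mu, w = mu)
         },
         binomial = {
           p <- plogis(eta)
           list(g = y - size * p, w = pmax(size * p * (1 - p), 1e-12))
         },
         lognormal = list(g = (y - eta) / v, w = 1 / v))
}

# Maximize sum_i loglik_i(offset + M theta) - 0.5 * sum(pdiag * theta^2).
# Returns the mode, the penalized objective, the unpenalized loglik, and the
# negative Hessian H = M'WM + diag(pdiag) (sparse).
newton_penalized <- function(M, offset, y, family, size = NULL, v = NULL,
                             pdiag, theta0 = NULL, tol = 1e-9,
                             max_iter = 200) {
  d <- ncol(M)
  theta <- theta0 %||% numeric(d)
  P <- Matrix::Diagonal(d, x = pdiag)
  obj <- function(th) {
    eta <- offset + as.vector(M %*% th)
    fam_loglik(family, y, eta, size, v) - 0.5 * sum(pdiag * th^2)
  }
  f <- obj(theta)
  for (it in seq_len(max_iter)) {
    eta <- offset + as.vector(M %*% theta)
    dv <- fam_deriv(family, y, eta, size, v)
    grad <- as.vector(Matrix::crossprod(M, dv$g)) - pdiag * theta
    H <- Matrix::forceSymmetric(Matrix::crossprod(M, M * dv$w) + P)
    if (max(abs(grad)) < tol * (1 + abs(f)))
      return(list(theta = theta, H = H, objective = f,
                  loglik = fam_loglik(family, y, eta, size, v),
                  iterations = it - 1L, converged = TRUE))
    step <- tryCatch(as.vector(Matrix::solve(H, grad)),
                     error = function(e)
                       abort(paste("singular joint Hessian:",
                                   conditionMessage(e))))
    s <- 1
    repeat {
      f_new <- obj(theta + s * step)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-12) abort("Newton step failed to improve the joint posterior")
    }
    theta <- theta + s * step
    f <- f_new
  }
  eta <- offset + as.vector(M %*% theta)
  list(theta = theta, H = H, objective = f,
       loglik = fam_loglik(family, y, eta, size, v),
       iterations = max_iter, converged = FALSE)
}

state_Z <- function(obs_state, state_levels, n) {
  Matrix::sparseMatrix(i = seq_len(n),
                       j = match(obs_state, state_levels),
                       x = 1, dims = c(n, length(state_levels)))
}

county_Z <- function(obs_county, N, n) {
  Matrix::sparseMatrix(i = seq_len(n), j = obs_county, x = 1,
                       dims = c(n, N))
}

#' Laplace-approximate marginal log-likelihood
#'
#' Evaluates the marginal log-likelihood of a fitted measure's data at given
#' fixed effects and variance components, integrating the state and county
#' random effects by the Laplace approximation: the integrand is maximized
#' by Newton iterations and the Gaussian curvature correction
#' `(q/2) log(2*pi) - (1/2) log det H` applied at the mode. A variance
#' component equal to zero pins its effects at zero (that block is excluded
#' from the integral). Useful for verifying that the optimizer's likelihood
#' at the returned estimates is at least the likelihood at any other
#' parameter value (e.g. the generating truth), and for cross-checking
#' against direct numerical integration on small problems.
#'
#' @param fit A converged `measure_fit`.
#' @param beta Fixed-effect vector (defaults to the fitted estimates).
#' @param sigma_state,sigma_county Random-effect standard deviations
#'   (default: fitted).
#' @return The approximate marginal log-likelihood (scalar).
#' @export
laplace_loglik <- function(fit, beta = NULL, sigma_state = NULL,
                           sigma_county = NULL) {
  ed <- fit$eb_data
  if (is.null(ed)) abort("fit carries no data (unconverged?)")
  beta <- beta %||% fit$beta$estimate
  sigma_state <- sigma_state %||% fit$sigma_state_hat
  sigma_county <- sigma_county %||% fit$sigma_county_hat
  if (sigma_state < 0 || sigma_county < 0) abort("negative sigma")
  n <- length(ed$y)
  offset <- (ed$offset %||% rep(0, n)) + as.vector(ed$X_obs %*% beta)

  blocks <- list()
  pdiag <- numeric(0)
  const <- 0
  if (sigma_state > 0) {
    Zs <- state_Z(ed$obs_state, fit$state_levels, n)
    blocks <- c(blocks, list(Zs))
    pdiag <- c(pdiag, rep(1 / sigma_state^2, fit$J))
    const <- const - fit$J / 2 * log(2 * pi * sigma_state^2)
  }
  if (sigma_county > 0) {
    Zc <- county_Z(ed$obs_county, fit$N, n)
    blocks <- c(blocks, list(Zc))
    pdiag <- c(pdiag, rep(1 / sigma_county^2, fit$N))
    const <- const - fit$N / 2 * log(2 * pi * sigma_county^2)
  }
  if (length(blocks) == 0) {
    return(fam_loglik(fit$family, ed$y, offset, ed$size, ed$v))
  }
  M <- do.call(cbind, blocks)
  res <- newton_penalized(M, offset, ed$y, fit$family, ed$size, ed$v, pdiag)
  q <- ncol(M)
  ldet <- 2 * sum(log(Matrix::diag(Matrix::chol(res$H))))
  res$objective + const + q / 2 * log(2 * pi) - ldet / 2
}

# Fallback maximum-likelihood fitter: maximizes the Laplace-approximate
# marginal likelihood directly over (beta, sigma_state, sigma_county) with
# box constraints sigma >= 0. Used when lme4's PIRLS stalls (e.g. an exactly
# constant response with very large effective counts).
ml_laplace <- function(family, y, X_obs, offset = NULL, size = NULL,
                       v = NULL, obs_state, state_levels, obs_county, N,
                       beta0 = NULL) {
  p <- ncol(X_obs)
  proto <- structure(list(
    family = family, converged = TRUE,
    J = length(state_levels), N = N, state_levels = state_levels,
    beta = tibble(term = colnames(X_obs), estimate = rep(0, p)),
    sigma_state_hat = 0.1, sigma_county_hat = 0.1,
    eb_data = list(y = y, offset = offset, size = size, v = v,
                   X_obs = X_obs, obs_state = obs_state,
                   obs_county = obs_county)), class = "measure_fit")
  if (is.null(beta0)) {
    yy <- switch(family,
                 binomial = pmin(pmax(y / size, 1e-6), 1 - 1e-6),
                 poisson = pmax(y, 0.5) / exp(offset),
                 lognormal = y)
    lin <- switch(family, binomial = qlogis(yy), poisson = log(yy),
                  lognormal = yy)
    beta0 <- stats::lm.fit(X_obs, lin)$coefficients
    beta0[is.na(beta0)] <- 0
  }
  obj <- function(par) {
    -laplace_loglik(proto, beta = par[seq_len(p)],
                    sigma_state = par[p + 1], sigma_county = par[p + 2])
  }
  opt <- stats::optim(c(beta0, 0.1, 0.1), obj, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), 0, 0),
                      control = list(maxit = 500))
  list(beta = setNames(opt$par[seq_len(p)], colnames(X_obs)),
       sigma_state = opt$par[p + 1], sigma_county = opt$par[p + 2],
       loglik = -opt$value, converged = opt$convergence == 0)
}
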