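#' Prior specification for the four-condition rating model
#'
#' Condition means get independent Uniform(mu_lower, mu_upper) priors and
#' condition standard deviations independent Uniform(sigma_lower,
#' sigma_upper) priors, both in VAS units; the 4x4 correlation matrix gets
#' an LKJ(eta) prior. The defaults are the full VAS range for means, half
#' the range for SDs, and eta = 1 (uniform over correlation matrices, the
#' least-informative member of the LKJ family).
#'
#' @param mu_lower,mu_upper Support of the mean priors (VAS units).
#' @param sigma_lower,sigma_upper Support of the SD priors (VAS units).
#' @param lkj_eta Positive LKJ shape; 1 is flat over correlation matrices.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_lower = 0, mu_upper = 100,
                       sigma_lower = 0, sigma_upper = 50,
                       lkj_eta = 1) {
  stopifnot(mu_lower < mu_upper, sigma_lower < sigma_upper, lkj_eta > 0)
  structure(list(mu_lower = mu_lower, mu_upper = mu_upper,
                 sigma_lower = sigma_lower, sigma_upper = sigma_upper,
                 lkj_eta = lkj_eta),
            class = "prior_spec")
}

# internal: validate a correlation matrix; returns its Cholesky factor
# (upper triangular) or signals an error
.chol_corr <- function(corr, what = "corr") {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-8)
    stop(what, " must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop(what, " must have a unit diagonal", call. = FALSE)
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch))
    stop(what, " must be positive definite", call. = FALSE)
  ch
}

#' Model parameters: means, SDs and a correlation matrix
#'
#' @param mu Numeric vector of condition means.
#' @param sigma Numeric vector of condition SDs (> 0), same length as `mu`.
#' @param corr Correlation matrix (symmetric, unit diagonal, positive
#'   definite) of matching dimension.
#' @return An object of class `model_params`.
#' @export
model_params <- function(mu, sigma, corr) {
  d <- length(mu)
  if (length(sigma) != d || nrow(corr) != d)
    stop("mu, sigma and corr dimensions must agree", call. = FALSE)
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  .chol_corr(corr)
  structure(list(mu = mu, sigma = sigma, corr = corr),
            class = "model_params")
}

#' Covariance matrix from SDs and a correlation matrix
#'
#' Returns `diag(sigma) %*% corr %*% diag(sigma)`, the variance-covariance
#' matrix implied by per-condition SDs and the correlation structure.
#'
#' @param sigma Vector of standard deviations (> 0).
#' @param corr Correlation matrix of matching dimension.
#' @return Symmetric positive-definite covariance matrix.
#' @export
build_covariance <- function(sigma, corr) {
  if (length(sigma) != nrow(corr))
    stop("sigma length must match corr dimension", call. = FALSE)
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  .chol_corr(corr)
  outer(sigma, sigma) * corr
}

#' Unnormalized LKJ log-density of a correlation matrix
#'
#' `(eta - 1) * log det(corr)`. The normalizing constant is omitted: MCMC
#' only needs the density up to a constant, and every use in this package
#' compares densities at fixed eta.
#'
#' @param corr Correlation matrix.
#' @param eta Positive shape parameter.
#' @return Unnormalized log-density (0 when `eta = 1`).
#' @export
lkj_log_density <- function(corr, eta) {
  stopifnot(eta > 0)
  ch <- .chol_corr(corr)
  (eta - 1) * 2 * sum(log(diag(ch)))
}

#' Joint log-prior of the model parameters
#'
#' Sum of the per-component Uniform log-densities for means and SDs plus
#' the (unnormalized) LKJ term. Parameters outside the prior support give
#' `-Inf` rather than an error, so samplers can evaluate freely.
#'
#' @param params A [model_params()] object.
#' @param priors A [prior_spec()] object.
#' @return Log-density; `-Inf` out of support.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  mu <- params$mu; sigma <- params$sigma
  if (any(mu <= priors$mu_lower) || any(mu >= priors$mu_upper) ||
      any(sigma <= priors$sigma_lower) || any(sigma >= priors$sigma_upper))
    return(-Inf)
  -length(mu) * log(priors$mu_upper - priors$mu_lower) -
    length(sigma) * log(priors$sigma_upper - priors$sigma_lower) +
    lkj_log_density(params$corr, priors$lkj_eta)
}

#' Multivariate-normal log-likelihood of a score matrix
#'
#' Sum over participant rows of the d-dimensional multivariate-normal
#' log-density with mean `params$mu` and covariance
#' `build_covariance(params$sigma, params$corr)`. Columns must be in the
#' canonical condition order (see [shape_levels()]).
#'
#' @param data Numeric n x d matrix, one row per participant.
#' @param params A [model_params()] object.
#' @return Total log-likelihood.
#' @export
mvn_log_likelihood <- function(data, params) {
  data <- as.matrix(data)
  d <- length(params$mu)
  if (ncol(data) != d)
    stop("data must have ", d, " columns in canonical condition order",
         call. = FALSE)
  sig <- build_covariance(params$sigma, params$corr)
  ch <- tryCatch(chol(sig), error = function(e)
    stop("covariance matrix is numerically singular", call. = FALSE))
  n <- nrow(data)
  centered <- t(data) - params$mu            # d x n
  z <- backsolve(ch, centered, transpose = TRUE)
  quad <- sum(z * z)
  -0.5 * n * d * log(2 * pi) - n * sum(log(diag(ch))) - 0.5 * quad
}

#' Log-posterior (up to a constant)
#'
#' `log_prior + mvn_log_likelihood`; `-Inf` from an out-of-support prior
#' short-circuits the likelihood.
#'
#' @inheritParams mvn_log_likelihood
#' @inheritParams log_prior
#' @return Log posterior density up to an additive constant.
#' @export
log_posterior <- function(data, params, priors = prior_spec()) {
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + mvn_log_likelihood(data, params)
}
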