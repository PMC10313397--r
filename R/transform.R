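# Bijection between the model's bounded parameter space and R^14, used by
# the sampler: scaled-logistic maps for means and SDs, and hyperbolic-
# tangent canonical partial correlations (CPCs) assembled recursively into
# a Cholesky factor for the correlation matrix. The CPC parameterization
# keeps the unconstrained space rectangular: any finite vector maps to a
# valid (positive-definite) correlation matrix.

# internal: lower-triangular index pairs (i > j) in row-major order,
# matching the corr21, corr31, corr32, ... naming
.lower_pairs <- function(d) {
  out <- NULL
  for (i in 2:d) for (j in seq_len(i - 1)) out <- rbind(out, c(i, j))
  out
}

#' Map model parameters to an unconstrained vector
#'
#' Inverse of [to_constrained()]. Means and SDs go through scaled logit
#' transforms onto the prior support; the correlation matrix is decomposed
#' into canonical partial correlations via its Cholesky factor, then
#' mapped by `atanh`.
#'
#' @param params A [model_params()] object interior to the prior support.
#' @param priors A [prior_spec()] giving the support bounds.
#' @return Numeric vector of length `2d + d(d-1)/2` (14 for d = 4).
#' @export
to_unconstrained <- function(params, priors = prior_spec()) {
  mu <- params$mu; sigma <- params$sigma; corr <- params$corr
  d <- length(mu)
  if (any(mu <= priors$mu_lower) || any(mu >= priors$mu_upper))
    stop("mu must be strictly inside the prior support", call. = FALSE)
  if (any(sigma <= priors$sigma_lower) || any(sigma >= priors$sigma_upper))
    stop("sigma must be strictly inside the prior support", call. = FALSE)
  x_mu <- stats::qlogis((mu - priors$mu_lower) /
                          (priors$mu_upper - priors$mu_lower))
  x_sigma <- stats::qlogis((sigma - priors$sigma_lower) /
                             (priors$sigma_upper - priors$sigma_lower))
  L <- t(.chol_corr(params$corr))
  pairs <- .lower_pairs(d)
  z <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rem <- 1 - if (j > 1) sum(L[i, seq_len(j - 1)]^2) else 0
    z[k] <- L[i, j] / sqrt(rem)
  }
  if (any(abs(z) >= 1))
    stop("correlation matrix is on the boundary of the support",
         call. = FALSE)
  c(x_mu, x_sigma, atanh(z))
}

#' Map an unconstrained vector back to model parameters
#'
#' Returns the constrained parameters together with the log absolute
#' determinant of the Jacobian of this map, which a sampler working on the
#' unconstrained space must add to the log-posterior. The correlation
#' block's Jacobian combines the `tanh` derivative with the known CPC-to-
#' correlation determinant, `prod (1 - z_ij^2)^((d-j-1)/2)` over
#' lower-triangular entries (column index j).
#'
#' @param x Finite numeric vector as produced by [to_unconstrained()].
#' @param priors A [prior_spec()].
#' @return List with elements `params` ([model_params()]) and
#'   `log_jacobian` (scalar).
#' @export
to_constrained <- function(x, priors = prior_spec()) {
  d <- 4L
  stopifnot(length(x) == 14L, all(is.finite(x)))
  p_mu <- stats::plogis(x[1:4])
  p_sig <- stats::plogis(x[5:8])
  w_mu <- priors$mu_upper - priors$mu_lower
  w_sig <- priors$sigma_upper - priors$sigma_lower
  mu <- priors$mu_lower + w_mu * p_mu
  sigma <- priors$sigma_lower + w_sig * p_sig
  z <- tanh(x[9:14])
  z <- pmin(pmax(z, -1 + 1e-12), 1 - 1e-12)  # avoid exact saturation
  pairs <- .lower_pairs(d)
  L <- diag(d)
  for (i in 2:d) {
    rem <- 1
    for (j in seq_len(i - 1)) {
      k <- which(pairs[, 1] == i & pairs[, 2] == j)
      L[i, j] <- z[k] * sqrt(rem)
      rem <- max(rem - L[i, j]^2, 1e-14)   # guard against tanh saturation
    }
    L[i, i] <- sqrt(rem)
  }
  corr <- L %*% t(L)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  # deep tanh saturation can make the product numerically singular even
  # though the CPC construction is positive definite in exact arithmetic;
  # shrink toward the identity only as far as needed to restore a valid
  # factorization (the density is vanishingly small out there anyway)
  for (delta in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    cand <- (1 - delta) * corr + delta * diag(d)
    if (!inherits(tryCatch(chol(cand), error = identity), "error")) {
      corr <- cand
      break
    }
  }
  lj <- sum(log(w_mu) + log(p_mu) + log1p(-p_mu)) +
    sum(log(w_sig) + log(p_sig) + log1p(-p_sig)) +
    sum((1 + (d - pairs[, 2] - 1) / 2) * log1p(-z^2))
  list(params = model_params(mu, sigma, corr), log_jacobian = lj)
}

# internal: flatten constrained params into the canonical 14-vector
# (mu1..4, sigma1..4, corr lower triangle row-major)
flatten_params <- function(params) {
  pairs <- .lower_pairs(length(params$mu))
  c(params$mu, params$sigma, params$corr[pairs])
}
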