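#' Expected a posteriori (posterior mean)
#'
#' Arithmetic mean over all retained draws pooled across chains.
#'
#' @param x Numeric vector of draws.
#' @return Scalar posterior mean.
#' @export
eap <- function(x) {
  if (length(x) == 0) stop("eap needs a non-empty draw vector", call. = FALSE)
  mean(x)
}

#' Posterior standard deviation
#'
#' Sample (n - 1 denominator) standard deviation over pooled draws.
#'
#' @param x Numeric vector with at least 2 draws.
#' @return Scalar SD.
#' @export
posterior_sd <- function(x) {
  if (length(x) < 2)
    stop("posterior_sd needs at least 2 draws", call. = FALSE)
  stats::sd(x)
}

#' Highest density interval (shortest interval)
#'
#' Sorts the draws and scans every contiguous window of
#' `ceiling(mass * n)` draws, returning the narrowest one; ties go to the
#' window with the smallest lower endpoint. Assumes a unimodal posterior,
#' which is the case for every marginal this model produces.
#'
#' @param x Numeric vector of at least 20 draws.
#' @param mass Probability mass of the interval, in (0, 1).
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  if (length(x) < 20)
    stop("hdi needs at least 20 draws", call. = FALSE)
  if (mass <= 0 || mass >= 1)
    stop("mass must be in (0, 1)", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  k <- ceiling(mass * n)
  if (k >= n) return(c(xs[1], xs[n]))
  lo <- xs[seq_len(n - k + 1)]
  hi <- xs[k:n]
  widths <- hi - lo
  i <- which.min(widths)   # which.min takes the first minimum: lowest lower end
  c(lower = lo[i], upper = hi[i])
}

#' Directional hypothesis probability from paired draws
#'
#' The posterior probability P(mu_i - mu_j > 0), estimated as the mean
#' over retained draws of the indicator that draw t of `draws_i` exceeds
#' draw t of `draws_j`. Ties count as 0 (the strict inequality fails).
#'
#' @param draws_i,draws_j Equal-length draw vectors paired by draw index.
#' @return Probability in \[0, 1\].
#' @export
directional_probability <- function(draws_i, draws_j) {
  if (length(draws_i) != length(draws_j))
    stop("draw vectors must have equal length", call. = FALSE)
  mean(draws_i - draws_j > 0)
}

#' Pairwise directional-probability matrix
#'
#' Entry (i, j) is the posterior probability that condition i's mean
#' exceeds condition j's, computed draw-wise; the diagonal is fixed at 0
#' by the reporting convention (self-comparison is meaningless).
#'
#' @param mu_draws Matrix of pooled draws, one column per condition in
#'   canonical order (or a list of four equal-length vectors).
#' @param labels Condition labels for dimnames.
#' @return 4x4 matrix of probabilities with zero diagonal.
#' @export
probability_matrix <- function(mu_draws, labels = shape_levels()) {
  if (is.list(mu_draws)) mu_draws <- do.call(cbind, mu_draws)
  k <- ncol(mu_draws)
  out <- matrix(0, k, k, dimnames = list(labels[seq_len(k)],
                                         labels[seq_len(k)]))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j)
      out[i, j] <- directional_probability(mu_draws[, i], mu_draws[, j])
  }
  out
}

#' Compound comparison specification
#'
#' Describes the joint hypothesis that both conditions in group A exceed
#' both conditions in group B, with no ordering claimed within either
#' group.
#'
#' @param group_a,group_b Integer pairs of condition indices; all four
#'   must be distinct.
#' @return Object of class `compound_spec`.
#' @export
compound_spec <- function(group_a, group_b) {
  idx <- c(group_a, group_b)
  if (length(group_a) != 2 || length(group_b) != 2 ||
      anyDuplicated(idx) || !all(idx %in% 1:4))
    stop("group_a and group_b must be disjoint pairs of condition indices",
         call. = FALSE)
  structure(list(group_a = as.integer(group_a),
                 group_b = as.integer(group_b)),
            class = "compound_spec")
}

#' Joint compound probability (draw-wise)
#'
#' Posterior probability that every condition in group A exceeds every
#' condition in group B, estimated as the EAP of the draw-wise product of
#' the four pairwise indicators. Because the four indicators are
#' evaluated on the same draw, posterior dependence between the means is
#' respected; this is generally not the product of the four marginal
#' probabilities.
#'
#' @param mu_draws Matrix of pooled condition-mean draws (columns =
#'   conditions in canonical order).
#' @param spec A [compound_spec()].
#' @return Probability in \[0, 1\].
#' @export
joint_probability <- function(mu_draws, spec) {
  if (!inherits(spec, "compound_spec"))
    stop("spec must be a compound_spec", call. = FALSE)
  if (is.list(mu_draws)) mu_draws <- do.call(cbind, mu_draws)
  ind <- rep(TRUE, nrow(mu_draws))
  for (a in spec$group_a) for (b in spec$group_b)
    ind <- ind & (mu_draws[, a] - mu_draws[, b] > 0)
  mean(ind)
}

#' Product of four marginal directional probabilities
#'
#' The plain product of four pairwise probabilities — the arithmetic used
#' in the study's printed compound summaries. It coincides with
#' [joint_probability()] only when the four events are independent, so
#' both are always reported side by side.
#'
#' @param p1,p2,p3,p4 Probabilities in \[0, 1\].
#' @return Their product.
#' @export
marginal_product <- function(p1, p2, p3, p4) {
  p <- c(p1, p2, p3, p4)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all inputs must be probabilities in [0, 1]", call. = FALSE)
  prod(p)
}

#' Posterior summary table
#'
#' One row per parameter: EAP, posterior SD and HDI bounds, the study's
#' reporting triple.
#'
#' @param draws A `posterior_draws` object.
#' @param mass HDI probability mass.
#' @return data.frame with columns parameter, eap, sd, hdi_lower,
#'   hdi_upper, mass.
#' @export
summarize_draws <- function(draws, mass = 0.95) {
  rows <- lapply(draws$param_names, function(p) {
    x <- pooled_draws(draws, p)
    h <- hdi(x, mass)
    data.frame(parameter = p, eap = eap(x), sd = posterior_sd(x),
               hdi_lower = h[[1]], hdi_upper = h[[2]], mass = mass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
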