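#' MCMC chain configuration
#'
#' Defaults follow the study protocol: five chains of 5,000 iterations
#' each with the first 1,000 discarded as burn-in, leaving
#' 5 x 4,000 = 20,000 retained draws to approximate the posterior.
#'
#' @param n_chains Number of independent chains (>= 2 for diagnostics).
#' @param n_iterations Iterations per chain.
#' @param burn_in Iterations discarded per chain (also the adaptation
#'   window of the proposal).
#' @param seed Master seed; chain c runs with `seed + c - 1`.
#' @param target_accept Acceptance rate the scale adaptation aims for
#'   (0.234 is the classic high-dimensional random-walk optimum).
#' @param init_scale Initial proposal standard deviation per coordinate.
#' @param updates_per_iteration Number of Metropolis updates composed
#'   into one iteration. One retained draw is stored per iteration
#'   regardless, so this trades computation for lower autocorrelation at
#'   a fixed draw count (as gradient samplers do with many leapfrog
#'   steps per iteration).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 5, n_iterations = 5000, burn_in = 1000,
                         seed = 1, target_accept = 0.234,
                         init_scale = 0.1, updates_per_iteration = 5) {
  stopifnot(n_chains >= 1, burn_in >= 1, burn_in < n_iterations,
            target_accept > 0, target_accept < 1, init_scale > 0,
            updates_per_iteration >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed),
                 target_accept = target_accept,
                 init_scale = init_scale,
                 updates_per_iteration = as.integer(updates_per_iteration)),
            class = "chain_config")
}

#' Run adaptive random-walk Metropolis chains
#'
#' Samples a target log-density over an unconstrained real vector with
#' independent chains. During burn-in the global proposal scale follows a
#' Robbins-Monro recursion toward `target_accept` and the proposal shape
#' is re-estimated from the chain history (Haario-style adaptive
#' Metropolis); both are frozen when sampling starts, so the retained
#' draws come from a fixed Markov kernel. If `transform` is supplied, each
#' retained draw is mapped through it (e.g. back to the constrained
#' parameter space); `transform` must return a vector of length
#' `length(param_names)`.
#'
#' @param log_target Function: numeric vector -> log-density (may return
#'   `-Inf`). When sampling a bounded model, fold the transform
#'   log-Jacobian into this target.
#' @param config A [chain_config()].
#' @param init Optional `n_chains x d` matrix of start points; by default
#'   each chain starts from an independent standard-normal draw under its
#'   own seed.
#' @param n_params Dimension d of the sampling space (required when
#'   `init` is missing).
#' @param transform Optional map from sampling space to reported
#'   parameters; identity if omitted.
#' @param param_names Names for the reported parameters.
#' @param indep_proposal Optional global proposal, a list with elements
#'   `mean` (d-vector), `scale_chol` (lower-triangular Cholesky factor of
#'   the proposal scale matrix) and `df` (Student-t degrees of freedom).
#'   When supplied, each iteration draws an independence proposal from
#'   this multivariate t with probability `indep_weight` and a random-walk
#'   proposal otherwise; the mixture keeps the random-walk's local
#'   robustness while the global component cuts autocorrelation. Typically
#'   built from a Laplace approximation at the posterior mode (see
#'   [laplace_proposal()]).
#' @param indep_weight Probability of an independence proposal per
#'   iteration when `indep_proposal` is given.
#' @return An object of class `posterior_draws`: list with `values`
#'   (`n_chains x n_retained x n_params` array), `param_names` and a
#'   `config` echo.
#' @export
run_mcmc <- function(log_target, config = chain_config(), init = NULL,
                     n_params = NULL, transform = NULL,
                     param_names = NULL, indep_proposal = NULL,
                     indep_weight = 0.5) {
  if (is.null(init)) {
    if (is.null(n_params))
      stop("supply init or n_params", call. = FALSE)
    d <- as.integer(n_params)
  } else {
    init <- as.matrix(init)
    if (nrow(init) != config$n_chains)
      stop("init must have one row per chain", call. = FALSE)
    d <- ncol(init)
  }
  if (is.null(transform)) transform <- identity
  n_ret <- config$n_iterations - config$burn_in
  probe <- transform(if (is.null(init)) numeric(d) else init[1, ])
  p_out <- length(probe)
  if (is.null(param_names))
    param_names <- if (!is.null(names(probe))) names(probe)
                   else paste0("x", seq_len(p_out))
  values <- array(NA_real_,
                  dim = c(config$n_chains, n_ret, p_out),
                  dimnames = list(NULL, NULL, param_names))
  accept <- matrix(0, config$n_chains, 2,
                   dimnames = list(NULL, c("walk", "indep")))

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    x <- if (is.null(init)) stats::rnorm(d) else init[ch, ]
    lp <- log_target(x)
    if (!is.finite(lp))
      stop("log target is not finite at the initial point of chain ", ch,
           " (init = ", paste(signif(x, 4), collapse = ", "), ")",
           call. = FALSE)
    if (!is.null(indep_proposal)) {
      # start the local component at the Laplace scale
      gm <- exp(mean(log(diag(indep_proposal$scale_chol))))
      shape <- indep_proposal$scale_chol / gm
      log_scale <- log(2.38 / sqrt(d) * gm)
    } else {
      log_scale <- log(config$init_scale)
      shape <- diag(d)          # lower Cholesky factor of proposal shape
    }
    run_mean <- numeric(d)
    run_ss <- matrix(0, d, d)   # centered sum of squares (Welford)
    n_seen <- 0L
    n_acc_burn <- 0L
    use_indep <- !is.null(indep_proposal)
    prop_ch <- indep_proposal   # chain-local copy; re-fitted at burn-in end
    if (use_indep) lq_x <- .mvt_logpdf(x, prop_ch)
    n_prop <- c(walk = 0, indep = 0); n_acc <- c(walk = 0, indep = 0)
    for (t in seq_len(config$n_iterations)) {
      for (u in seq_len(config$updates_per_iteration)) {
        indep_step <- use_indep && stats::runif(1) < indep_weight
        if (indep_step) {
          prop <- .mvt_draw(prop_ch)
          lq_prop <- .mvt_logpdf(prop, prop_ch)
          lp_prop <- log_target(prop)
          log_ratio <- lp_prop - lp + lq_x - lq_prop
        } else {
          prop <- x + exp(log_scale) * as.vector(shape %*% stats::rnorm(d))
          lp_prop <- log_target(prop)
          log_ratio <- lp_prop - lp
        }
        alpha <- if (is.finite(lp_prop)) min(1, exp(log_ratio)) else 0
        kind <- if (indep_step) "indep" else "walk"
        n_prop[kind] <- n_prop[kind] + 1
        if (stats::runif(1) < alpha) {
          n_acc[kind] <- n_acc[kind] + 1
          x <- prop; lp <- lp_prop
          if (use_indep) lq_x <- if (indep_step) lq_prop
                                 else .mvt_logpdf(x, prop_ch)
          if (t <= config$burn_in) n_acc_burn <- n_acc_burn + 1L
        }
        if (t <= config$burn_in) {
          if (!indep_step)
            log_scale <- log_scale +
              (alpha - config$target_accept) / max(1, t)^0.6
          n_seen <- n_seen + 1L
          delta <- x - run_mean
          run_mean <- run_mean + delta / n_seen
          run_ss <- run_ss + tcrossprod(delta, x - run_mean)
        }
      }
      if (t <= config$burn_in) {
        if (n_seen >= max(50L, 2L * d) && t %% 50L == 0L) {
          cov_est <- run_ss / (n_seen - 1L) + diag(1e-8, d)
          shape_try <- tryCatch(t(chol(cov_est)), error = function(e) NULL)
          if (!is.null(shape_try)) {
            # renormalize so log_scale keeps its meaning as overall size
            shape <- shape_try / exp(mean(log(diag(shape_try))))
          }
        }
        if (t == config$burn_in && n_acc_burn == 0L)
          stop("chain ", ch, " accepted no proposals during adaptation; ",
               "check the target or init_scale", call. = FALSE)
      } else {
        values[ch, t - config$burn_in, ] <- transform(x)
      }
    }
    accept[ch, ] <- ifelse(n_prop > 0, n_acc / n_prop, NA)
  }
  structure(list(values = values, param_names = param_names,
                 config = config, accept_rates = accept),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  dm <- dim(x$values)
  cat("posterior_draws:", dm[1], "chains x", dm[2], "retained draws x",
      dm[3], "parameters\n")
  cat("parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Total number of retained draws (all chains pooled)
#' @param draws A `posterior_draws` object.
#' @return Integer count.
#' @export
n_retained <- function(draws) {
  dm <- dim(draws$values)
  as.integer(dm[1] * dm[2])
}

#' Pooled draws of one parameter
#'
#' Flattens one parameter's draws across chains. The flattening order is
#' fixed (chains interleaved identically for every parameter), so draw t
#' of one parameter is paired with draw t of any other — the pairing the
#' draw-wise indicator probabilities rely on.
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name or index.
#' @return Numeric vector of length `n_retained(draws)`.
#' @export
pooled_draws <- function(draws, parameter) {
  as.vector(draws$values[, , parameter])
}

# internal: pooled n x 4 matrix of the four condition-mean draws
mu_draw_matrix <- function(draws) {
  sapply(paste0("mu", 1:4), function(p) pooled_draws(draws, p))
}

# internal: multivariate Student-t log-density (proposal bookkeeping)
.mvt_logpdf <- function(x, prop) {
  d <- length(x)
  z <- forwardsolve(prop$scale_chol, x - prop$mean)
  q <- sum(z * z)
  lgamma((prop$df + d) / 2) - lgamma(prop$df / 2) -
    (d / 2) * log(prop$df * pi) - sum(log(diag(prop$scale_chol))) -
    ((prop$df + d) / 2) * log1p(q / prop$df)
}

# internal: one draw from the multivariate Student-t proposal
.mvt_draw <- function(prop) {
  d <- length(prop$mean)
  z <- stats::rnorm(d)
  w <- sqrt(prop$df / stats::rchisq(1, prop$df))
  prop$mean + w * as.vector(prop$scale_chol %*% z)
}

#' Save / load posterior draws as columnar text
#'
#' Writes one CSV with `chain` and `iteration` columns followed by one
#' column per parameter; the chain configuration travels along as a
#' JSON comment line, so a saved file fully determines its provenance.
#'
#' @param draws A `posterior_draws` object.
#' @param path File path (conventionally `.csv`).
#' @return `load_draws` returns the reconstructed `posterior_draws`.
#' @export
save_draws <- function(draws, path) {
  dm <- dim(draws$values)
  flat <- do.call(rbind, lapply(seq_len(dm[1]), function(ch) {
    data.frame(chain = ch, iteration = seq_len(dm[2]),
               matrix(draws$values[ch, , ], dm[2], dm[3]))
  }))
  names(flat) <- c("chain", "iteration", draws$param_names)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config: ",
                    jsonlite::toJSON(unclass(draws$config),
                                     auto_unbox = TRUE, null = "null")),
             con)
  utils::write.csv(flat, con, row.names = FALSE)
  invisible(path)
}

#' @rdname save_draws
#' @export
load_draws <- function(path) {
  header <- readLines(path, n = 1)
  config <- NULL
  if (startsWith(header, "# config: ")) {
    config <- jsonlite::fromJSON(sub("^# config: ", "", header))
    class(config) <- "chain_config"
  }
  flat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  pn <- setdiff(names(flat), c("chain", "iteration"))
  chains <- sort(unique(flat$chain))
  n_it <- max(flat$iteration)
  values <- array(NA_real_, c(length(chains), n_it, length(pn)),
                  dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(chains)) {
    sub <- flat[flat$chain == chains[ch], ]
    sub <- sub[order(sub$iteration), ]
    values[ch, , ] <- as.matrix(sub[, pn])
  }
  structure(list(values = values, param_names = pn, config = config),
            class = "posterior_draws")
}

#' Laplace approximation as a global proposal
#'
#' Finds the mode of `log_target` by quasi-Newton optimization from
#' `start`, takes the negative inverse Hessian at the mode as a
#' covariance, and packages mode and (slightly inflated) covariance as a
#' multivariate Student-t proposal for [run_mcmc()]'s independence
#' component. Heavy t tails (small `df`) keep the importance ratio
#' bounded when the posterior is wider than the quadratic approximation.
#'
#' @param log_target Log-density over the unconstrained space.
#' @param start Finite start vector for the optimizer.
#' @param df Proposal degrees of freedom.
#' @param inflate Scale multiplier applied to the Laplace covariance.
#' @return List with `mean`, `scale_chol` (lower Cholesky), `df`.
#' @export
laplace_proposal <- function(log_target, start, df = 4, inflate = 1.2) {
  neg <- function(x) {
    v <- log_target(x)
    if (is.finite(v)) -v else 1e10   # finite penalty keeps BFGS moving
  }
  opt <- stats::optim(start, neg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  hess <- stats::optimHess(opt$par, neg)
  hess <- (hess + t(hess)) / 2
  ev <- eigen(hess, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-8)
  cov <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
  cov <- inflate^2 * (cov + t(cov)) / 2
  list(mean = opt$par, scale_chol = t(chol(cov)), df = df)
}
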