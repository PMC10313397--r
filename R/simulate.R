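# Synthetic within-subjects VAS datasets. The generator draws each
# participant's four condition scores for a taste from a multivariate
# normal whose mean, SDs and correlation structure are the model's own
# assumptions, so the inference pipeline can be validated end-to-end with
# no external data.

#' Generative ("true") parameters for one taste
#'
#' @param mu 4-vector of condition means in VAS units, each in \[0, 100\].
#' @param sigma 4-vector of condition SDs (> 0).
#' @param corr 4x4 correlation matrix.
#' @param taste_label One of [taste_levels()].
#' @return Object of class `true_params` (also a valid [model_params()]).
#' @export
true_params <- function(mu, sigma, corr, taste_label) {
  taste_label <- match.arg(taste_label, taste_levels())
  if (any(mu < 0) || any(mu > 100))
    stop("mu must lie in [0, 100]", call. = FALSE)
  p <- model_params(mu, sigma, corr)
  p$taste_label <- taste_label
  class(p) <- c("true_params", class(p))
  p
}

#' Simulation configuration
#'
#' @param n_participants Number of participants (>= 1); the study used 24.
#' @param seed Master RNG seed; taste- and order-level substreams are
#'   derived from it by fixed offsets.
#' @param bounds_mode How to handle the \[0, 100\] VAS bounds:
#'   `"clipped"` (default) clamps draws to the scale, `"unbounded"`
#'   leaves them as drawn (the only mode whose moments exactly match the
#'   plain multivariate-normal inference model), `"truncated"` redraws a
#'   participant's 4-vector until all components are in range.
#' @param rounding Round scores to integers, emulating a discrete slider.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 24, seed = 1,
                       bounds_mode = c("clipped", "unbounded", "truncated"),
                       rounding = FALSE) {
  bounds_mode <- match.arg(bounds_mode)
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 bounds_mode = bounds_mode,
                 rounding = isTRUE(rounding)),
            class = "sim_config")
}

# internal: all permutations of seq_len(n) in lexicographic row order
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Latin-square style presentation orders
#'
#' Enumerates all 4! = 24 permutations of the four condition labels in
#' lexicographic order, shuffles that enumeration under the seed, and
#' assigns orders to participants by cycling through it. At
#' `n_participants = 24` every permutation is used exactly once, so each
#' condition occupies each serial position exactly 6 times.
#'
#' @param n_participants Number of orders to produce (>= 1).
#' @param seed RNG seed for the shuffle.
#' @return `n_participants x 4` character matrix; row p is participant
#'   p's consumption order.
#' @export
generate_orders <- function(n_participants, seed = 1) {
  if (length(n_participants) != 1 || n_participants < 1)
    stop("n_participants must be a positive integer", call. = FALSE)
  perms <- .permutations(4L)
  set.seed(seed)
  perms <- perms[sample.int(nrow(perms)), , drop = FALSE]
  idx <- ((seq_len(n_participants) - 1L) %% nrow(perms)) + 1L
  labels <- shape_levels()
  matrix(labels[perms[idx, , drop = FALSE]], nrow = n_participants,
         dimnames = list(NULL, paste0("position", 1:4)))
}

# internal: n draws from N(mu, diag(sigma) corr diag(sigma)) via Cholesky
.rmvn <- function(n, mu, sigma, corr) {
  ch <- .chol_corr(corr)
  z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(z %*% ch * rep(sigma, each = n), 2, mu, "+")
}

#' Simulate a complete within-subjects ratings table
#'
#' For each participant and taste, draws a correlated 4-vector of
#' condition scores from the multivariate normal defined by that taste's
#' [true_params()], applies the configured bounds handling, and attaches
#' presentation-order positions from [generate_orders()]. The output is
#' the long-format ratings table the pipeline consumes: exactly
#' `n_participants * 4 * n_tastes` rows.
#'
#' @param params_per_taste List of [true_params()], one per taste.
#' @param config A [sim_config()].
#' @return data.frame with columns participant_id, order_position,
#'   shape, taste, score.
#' @export
simulate_ratings <- function(params_per_taste, config = sim_config()) {
  if (!length(params_per_taste))
    stop("params_per_taste must contain at least one true_params",
         call. = FALSE)
  n <- config$n_participants
  orders <- generate_orders(n, seed = config$seed)
  labels <- shape_levels()
  pos <- t(apply(orders, 1, function(o) match(labels, o)))
  ids <- sprintf("P%02d", seq_len(n))
  out <- list()
  for (k in seq_along(params_per_taste)) {
    tp <- params_per_taste[[k]]
    if (!inherits(tp, "true_params"))
      stop("params_per_taste entries must be true_params objects",
           call. = FALSE)
    set.seed(config$seed + 1000L * k)
    scores <- .rmvn(n, tp$mu, tp$sigma, tp$corr)
    if (config$bounds_mode == "clipped") {
      scores <- pmin(pmax(scores, 0), 100)
    } else if (config$bounds_mode == "truncated") {
      bad <- which(apply(scores, 1, function(r) any(r < 0 | r > 100)))
      while (length(bad)) {
        scores[bad, ] <- .rmvn(length(bad), tp$mu, tp$sigma, tp$corr)
        bad <- bad[apply(scores[bad, , drop = FALSE], 1,
                         function(r) any(r < 0 | r > 100))]
      }
    }
    if (config$rounding) scores <- round(scores)
    out[[k]] <- data.frame(
      participant_id = rep(ids, times = 4),
      order_position = as.vector(pos),
      shape = rep(labels, each = n),
      taste = tp$taste_label,
      score = as.vector(scores),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Study-like synthetic dataset
#'
#' Convenience fixture emulating the original study design: 24
#' participants, all three tastes, generator means set to the reported
#' EAP point estimates ([reference_means()]), a common SD and an
#' exchangeable correlation across the four conditions, clipped to the
#' VAS scale.
#'
#' @param seed Master seed.
#' @param sigma Common condition SD (VAS units).
#' @param rho Common pairwise correlation between condition scores.
#' @param n_participants Number of participants.
#' @return Long-format ratings data.frame (288 rows at the defaults).
#' @export
make_study_dataset <- function(seed = 1, sigma = 20, rho = 0.5,
                               n_participants = 24) {
  corr <- matrix(rho, 4, 4); diag(corr) <- 1
  mus <- reference_means()
  params <- lapply(taste_levels(), function(tst)
    true_params(mus[[tst]], rep(sigma, 4), corr, tst))
  simulate_ratings(params,
                   sim_config(n_participants = n_participants, seed = seed,
                              bounds_mode = "clipped"))
}
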