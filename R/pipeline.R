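# End-to-end study pipeline: validate ratings, fit the per-taste model,
# evaluate the six directional hypotheses and the compound Bouba-vs-Kiki
# comparisons, and render the report tables.

#' Validate a ratings table
#'
#' Enforces the study's data contract: canonical shape and taste labels,
#' scores within the VAS range, order positions in 1-4, and a complete
#' crossed design (every participant has exactly one score per
#' shape x taste).
#'
#' @param table data.frame with columns participant_id, order_position,
#'   shape, taste, score.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_ratings <- function(table) {
  req <- c("participant_id", "order_position", "shape", "taste", "score")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_shape <- !table$shape %in% shape_levels()
  if (any(bad_shape))
    stop("unknown shape label in row(s) ",
         paste(utils::head(which(bad_shape), 5), collapse = ", "), ": ",
         paste(unique(table$shape[bad_shape]), collapse = ", "),
         call. = FALSE)
  bad_taste <- !table$taste %in% taste_levels()
  if (any(bad_taste))
    stop("unknown taste label in row(s) ",
         paste(utils::head(which(bad_taste), 5), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(table$score) | table$score < 0 | table$score > 100))
    stop("scores must lie in [0, 100]", call. = FALSE)
  if (any(!table$order_position %in% 1:4))
    stop("order_position must be in 1..4", call. = FALSE)
  key <- interaction(table$participant_id, table$shape, table$taste,
                     drop = FALSE)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (participant, shape, taste) records: ",
         paste(utils::head(unique(key[dup]), 5), collapse = ", "),
         call. = FALSE)
  ids <- unique(table$participant_id)
  expected <- expand.grid(participant_id = ids, shape = shape_levels(),
                          taste = unique(table$taste),
                          stringsAsFactors = FALSE)
  got <- paste(table$participant_id, table$shape, table$taste)
  want <- paste(expected$participant_id, expected$shape, expected$taste)
  miss <- setdiff(want, got)
  if (length(miss))
    stop("incomplete design; missing (participant shape taste): ",
         paste(utils::head(miss, 5), collapse = "; "), call. = FALSE)
  invisible(table)
}

#' Write / read a ratings table as CSV
#'
#' UTF-8 comma-separated values with the canonical header
#' `participant_id, order_position, shape, taste, score`.
#'
#' @param table A validated ratings data.frame.
#' @param path File path.
#' @return `read_ratings` returns the validated table.
#' @export
write_ratings <- function(table, path) {
  validate_ratings(table)
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_ratings(tab)
  tab
}

# internal: pivot one taste's long records to an n x 4 matrix in
# canonical condition order
pivot_scores <- function(table, taste) {
  taste <- match.arg(taste, taste_levels())
  sub <- table[table$taste == taste, ]
  if (!nrow(sub)) stop("no records for taste ", taste, call. = FALSE)
  ids <- sort(unique(sub$participant_id))
  m <- sapply(shape_levels(), function(s) {
    rows <- sub[sub$shape == s, ]
    rows$score[match(ids, rows$participant_id)]
  })
  rownames(m) <- ids
  m
}

#' Fit the four-condition model to one taste
#'
#' Pivots the taste's scores to an n x 4 matrix in canonical condition
#' order, samples the posterior with adaptive Metropolis on the
#' unconstrained space (prior draws as start points, transform
#' log-Jacobian folded into the target), and runs the split-R-hat
#' convergence check. A convergence violation is reported as a warning,
#' never an error.
#'
#' @param table Validated ratings table.
#' @param taste One of [taste_levels()].
#' @param priors A [prior_spec()].
#' @param chains A [chain_config()].
#' @param r_hat_threshold Tolerance for [check_convergence()].
#' @return List of class `taste_fit`: `taste`, `draws`
#'   (`posterior_draws` in constrained space), `convergence`
#'   (`convergence_report`), `data` (the score matrix).
#' @export
fit_taste <- function(table, taste, priors = prior_spec(),
                      chains = chain_config(), r_hat_threshold = 0.01) {
  validate_ratings(table)
  scores <- pivot_scores(table, taste)
  fit_scores(scores, taste = taste, priors = priors, chains = chains,
             r_hat_threshold = r_hat_threshold)
}

#' Fit the model directly to an n x 4 score matrix
#'
#' The sampling core behind [fit_taste()], usable on raw matrices (for
#' example unbounded synthetic scores in parameter-recovery studies,
#' which the ratings-table validation would reject). Columns must follow
#' the canonical condition order.
#'
#' @param scores Numeric n x 4 matrix, one participant per row.
#' @inheritParams fit_taste
#' @return A `taste_fit` list; see [fit_taste()].
#' @export
fit_scores <- function(scores, taste = "sweetness", priors = prior_spec(),
                       chains = chain_config(), r_hat_threshold = 0.01) {
  scores <- as.matrix(scores)
  target <- function(x) {
    # numerically singular covariances (tanh saturation at extreme
    # proposals) are out of support, not errors, for the sampler
    tryCatch({
      tc <- to_constrained(x, priors)
      log_posterior(scores, tc$params, priors) + tc$log_jacobian
    }, error = function(e) -Inf)
  }
  # moment-based start for the mode search: sample means/SDs (kept
  # interior to the prior support) and a shrunk sample correlation
  start_mu <- pmin(pmax(colMeans(scores), priors$mu_lower + 1),
                   priors$mu_upper - 1)
  start_sd <- pmin(pmax(apply(scores, 2, stats::sd),
                        priors$sigma_lower + 1), priors$sigma_upper - 1)
  start_corr <- 0.7 * stats::cor(scores) + 0.3 * diag(4)
  start <- to_unconstrained(model_params(start_mu, start_sd, start_corr),
                            priors)
  proposal <- laplace_proposal(target, start)
  # two pilot stages refine the global proposal with the posterior's own
  # moments: the Laplace curvature alone understates the spread of the
  # SD and correlation blocks, and the second stage re-estimates the
  # moments under an already well-mixing kernel
  pd <- NULL
  for (stage in 1:2) {
    pilot_cfg <- chain_config(n_chains = 3, n_iterations = 2500,
                              burn_in = 500,
                              seed = chains$seed + 563L * stage,
                              updates_per_iteration = 1)
    set.seed(chains$seed + 104729L + stage)
    pilot_init <- if (is.null(pd))
      t(replicate(pilot_cfg$n_chains, .mvt_draw(proposal)))
    else pd[sample.int(nrow(pd), pilot_cfg$n_chains), , drop = FALSE]
    pilot <- run_mcmc(target, pilot_cfg, init = pilot_init,
                      indep_proposal = proposal)
    pd <- apply(pilot$values, 3, as.vector)
    cov_p <- 1.05^2 * (stats::cov(pd) + diag(1e-8, ncol(pd)))
    proposal <- list(mean = colMeans(pd), scale_chol = t(chol(cov_p)),
                     df = 10)
  }
  # warm starts: spread the official chains over pilot posterior draws
  set.seed(chains$seed + 7919L)
  init <- pd[sample.int(nrow(pd), chains$n_chains), , drop = FALSE]
  draws <- run_mcmc(target, chains, init = init,
                    indep_proposal = proposal, indep_weight = 0.85,
                    transform = function(x)
                      flatten_params(to_constrained(x, priors)$params),
                    param_names = param_names())
  conv <- check_convergence(draws, r_hat_threshold)
  if (!conv$pass)
    warning("convergence check failed for taste ", taste, ": max |R-hat-1| = ",
            format(conv$max_deviation, digits = 3), call. = FALSE)
  structure(list(taste = taste, draws = draws, convergence = conv,
                 data = scores),
            class = "taste_fit")
}

#' Fit all three tastes
#'
#' Runs [fit_taste()] per taste with taste-specific chain seeds derived
#' from the master seed, mirroring the study's three separate
#' four-dimensional fits.
#'
#' @inheritParams fit_taste
#' @return Named list of `taste_fit` objects.
#' @export
fit_all_tastes <- function(table, priors = prior_spec(),
                           chains = chain_config(),
                           r_hat_threshold = 0.01) {
  fits <- lapply(seq_along(taste_levels()), function(k) {
    cfg <- chains
    cfg$seed <- chains$seed + 100L * (k - 1L)
    fit_taste(table, taste_levels()[k], priors, cfg, r_hat_threshold)
  })
  names(fits) <- taste_levels()
  fits
}

# The six preregistered directional hypotheses.  mu indices follow the
# canonical order (1 Bouba-A6, 2 Kiki-A6, 3 Bouba-S6, 4 Kiki-A10).
hypothesis_table <- function() {
  data.frame(
    id = paste0("H", 1:6),
    taste = c("sweetness", "sourness", "bitterness",
              "sweetness", "sourness", "bitterness"),
    greater = c(1L, 2L, 2L, 3L, 4L, 4L),
    lesser = c(2L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the six directional hypotheses
#'
#' H1: Bouba-A6 sweeter than Kiki-A6; H2: Kiki-A6 more sour than
#' Bouba-A6; H3: Kiki-A6 more bitter than Bouba-A6; H4: Bouba-S6 sweeter
#' than Bouba-A6; H5: Kiki-A10 more sour than Kiki-A6; H6: Kiki-A10 more
#' bitter than Kiki-A6. Each probability is the draw-wise directional
#' probability from the corresponding taste's posterior.
#'
#' @param fits Named list of `taste_fit` objects (or `posterior_draws`),
#'   with names covering all of [taste_levels()].
#' @return data.frame with columns id, taste, comparison, probability.
#' @export
evaluate_hypotheses <- function(fits) {
  missing_t <- setdiff(taste_levels(), names(fits))
  if (length(missing_t))
    stop("missing draws for taste(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  ht <- hypothesis_table()
  lv <- shape_levels()
  ht$comparison <- paste(lv[ht$greater], ">", lv[ht$lesser])
  ht$probability <- vapply(seq_len(nrow(ht)), function(r) {
    dr <- fits[[ht$taste[r]]]
    if (inherits(dr, "taste_fit")) dr <- dr$draws
    m <- mu_draw_matrix(dr)
    directional_probability(m[, ht$greater[r]], m[, ht$lesser[r]])
  }, numeric(1))
  ht[, c("id", "taste", "comparison", "probability")]
}

#' Compound Bouba-vs-Kiki comparison per taste
#'
#' For each taste, evaluates the joint hypothesis that both shapes of
#' one family exceed both shapes of the other — Bouba over Kiki for
#' sweetness, Kiki over Bouba for sourness and bitterness — reporting
#' both the draw-wise [joint_probability()] and the
#' [marginal_product()] of the four pairwise probabilities.
#'
#' @inheritParams evaluate_hypotheses
#' @return data.frame with columns taste, direction, joint_probability,
#'   marginal_product.
#' @export
compound_report <- function(fits) {
  missing_t <- setdiff(taste_levels(), names(fits))
  if (length(missing_t))
    stop("missing draws for taste(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  bouba <- c(1L, 3L); kiki <- c(2L, 4L)
  rows <- lapply(taste_levels(), function(tst) {
    dr <- fits[[tst]]
    if (inherits(dr, "taste_fit")) dr <- dr$draws
    m <- mu_draw_matrix(dr)
    if (tst == "sweetness") {
      spec <- compound_spec(bouba, kiki); dir <- "Bouba > Kiki"
      ga <- bouba; gb <- kiki
    } else {
      spec <- compound_spec(kiki, bouba); dir <- "Kiki > Bouba"
      ga <- kiki; gb <- bouba
    }
    pm <- probability_matrix(m)
    marg <- marginal_product(pm[ga[1], gb[1]], pm[ga[1], gb[2]],
                             pm[ga[2], gb[1]], pm[ga[2], gb[2]])
    data.frame(taste = tst, direction = dir,
               joint_probability = joint_probability(m, spec),
               marginal_product = marg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format an estimate the way the study reports it
#'
#' `"EAP (SD) [HDI lower, HDI upper]"` with EAP/SD/HDI at 2 decimals,
#' e.g. `"38.52 (3.59) [31.21, 45.27]"`.
#'
#' @param eap,sd,lower,upper Scalars.
#' @return Character string.
#' @export
format_estimate <- function(eap, sd, lower, upper) {
  sprintf("%.2f (%.2f) [%.2f, %.2f]", eap, sd, lower, upper)
}

#' Assemble the full report bundle
#'
#' Collects per-taste posterior summaries, directional-probability
#' matrices (3 decimals in the rendering), convergence reports,
#' hypothesis results and compound probabilities, together with seed and
#' version provenance. Deterministic given the draws.
#'
#' @param fits Named list of `taste_fit` objects for all three tastes.
#' @param seed The master seed used upstream, recorded as provenance.
#' @return List of class `report_bundle`.
#' @export
build_report <- function(fits, seed = NA_integer_) {
  summaries <- lapply(fits, function(f) summarize_draws(f$draws))
  matrices <- lapply(fits, function(f)
    probability_matrix(mu_draw_matrix(f$draws)))
  convergence <- lapply(fits, function(f) {
    list(max_deviation = f$convergence$max_deviation,
         threshold = f$convergence$threshold,
         pass = f$convergence$pass,
         violations = f$convergence$violations)
  })
  structure(list(
    summaries = summaries,
    probability_matrices = matrices,
    convergence = convergence,
    hypotheses = evaluate_hypotheses(fits),
    compound = compound_report(fits),
    provenance = list(seed = seed,
                      package_version =
                        as.character(utils::packageVersion("boubataste")),
                      config = fits[[1]]$draws$config)
  ), class = "report_bundle")
}

#' Render a report bundle as markdown
#'
#' Human-readable rendering: per-taste estimate strings in the
#' `"EAP (SD) [lower, upper]"` convention and probability matrices at 3
#' decimals.
#'
#' @param report A `report_bundle`.
#' @return Character vector of markdown lines.
#' @export
render_report_markdown <- function(report) {
  lines <- c("# Shape-taste rating analysis report", "")
  for (tst in names(report$summaries)) {
    s <- report$summaries[[tst]]
    lines <- c(lines, paste0("## ", tst), "", "Condition mean estimates:")
    for (i in 1:4) {
      r <- s[s$parameter == paste0("mu", i), ]
      lines <- c(lines, paste0("- ", shape_levels()[i], ": ",
                               format_estimate(r$eap, r$sd, r$hdi_lower,
                                               r$hdi_upper)))
    }
    m <- report$probability_matrices[[tst]]
    lines <- c(lines, "", "P(row rated higher than column):", "",
               paste(c("| |", paste(colnames(m), "|")), collapse = " "),
               paste(rep("|---", 5), collapse = ""), "")
    for (i in 1:4) {
      lines <- c(lines, paste0("| ", rownames(m)[i], " | ",
                               paste(sprintf("%.3f", m[i, ]),
                                     collapse = " | "), " |"))
    }
    cv <- report$convergence[[tst]]
    lines <- c(lines, "",
               sprintf("Convergence: max |R-hat - 1| = %.4f (%s)",
                       cv$max_deviation,
                       if (cv$pass) "pass" else "FAIL"), "")
  }
  lines <- c(lines, "## Hypotheses", "")
  h <- report$hypotheses
  for (r in seq_len(nrow(h)))
    lines <- c(lines, sprintf("- %s (%s, %s): %.3f", h$id[r], h$taste[r],
                              h$comparison[r], h$probability[r]))
  lines <- c(lines, "", "## Compound Bouba-vs-Kiki comparisons", "")
  cp <- report$compound
  for (r in seq_len(nrow(cp)))
    lines <- c(lines, sprintf(
      "- %s (%s): joint %.3f, marginal product %.3f", cp$taste[r],
      cp$direction[r], cp$joint_probability[r], cp$marginal_product[r]))
  lines
}

#' Write a report bundle to JSON
#'
#' @param report A `report_bundle`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    summaries = lapply(report$summaries, function(s) s),
    probability_matrices = report$probability_matrices,
    convergence = report$convergence,
    hypotheses = report$hypotheses,
    compound = report$compound,
    provenance = report$provenance[c("seed", "package_version")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
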