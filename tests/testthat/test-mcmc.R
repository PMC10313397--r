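test_that("sampler recovers isotropic standard-normal moments", {
  target <- function(x) -0.5 * sum(x^2)
  draws <- run_mcmc(target,
                    chain_config(n_chains = 4, n_iterations = 7000,
                                 burn_in = 1000, seed = 42),
                    n_params = 2)
  for (p in draws$param_names) {
    x <- pooled_draws(draws, p)
    expect_lt(abs(mean(x)), 0.05)
    expect_lt(abs(var(x) - 1), 0.1)
  }
})

test_that("sampler matches the conjugate normal-mean posterior", {
  # y_i ~ N(theta, 4), theta ~ N(0, 100): posterior is closed form
  set.seed(5)
  y <- rnorm(12, 3, 2)
  post_var <- 1 / (1 / 100 + 12 / 4)
  post_mean <- post_var * sum(y) / 4
  target <- function(x) -0.5 * x^2 / 100 - sum((y - x)^2) / 8
  draws <- run_mcmc(target,
                    chain_config(n_chains = 4, n_iterations = 6000,
                                 burn_in = 1000, seed = 17),
                    n_params = 1)
  x <- pooled_draws(draws, "x1")
  q <- quantile(x, c(0.025, 0.5, 0.975))
  q_true <- qnorm(c(0.025, 0.5, 0.975), post_mean, sqrt(post_var))
  expect_true(all(abs(q - q_true) < 0.15 * sqrt(post_var)))
})

test_that("default configuration retains 5 x 4000 = 20000 draws", {
  draws <- run_mcmc(function(x) -0.5 * sum(x^2), chain_config(seed = 1),
                    n_params = 1)
  expect_equal(dim(draws$values)[1:2], c(5L, 4000L))
  expect_equal(n_retained(draws), 20000L)
})

test_that("sampling is reproducible and seed changes pooled summaries only within MC error", {
  target <- function(x) -0.5 * sum(x^2)
  cfg <- chain_config(n_chains = 3, n_iterations = 2000, burn_in = 500,
                      seed = 7)
  d1 <- run_mcmc(target, cfg, n_params = 2)
  d2 <- run_mcmc(target, cfg, n_params = 2)
  expect_identical(d1$values, d2$values)
  cfg2 <- cfg; cfg2$seed <- 8L
  d3 <- run_mcmc(target, cfg2, n_params = 2)
  expect_false(identical(d1$values, d3$values))
  expect_lt(abs(mean(pooled_draws(d1, "x1")) -
                  mean(pooled_draws(d3, "x1"))), 0.15)
})

test_that("non-finite targets at initialization are reported", {
  target <- function(x) if (x[1] < 0) -Inf else -0.5 * sum(x^2)
  expect_error(
    run_mcmc(target, chain_config(n_chains = 2, n_iterations = 100,
                                  burn_in = 10, seed = 1),
             init = matrix(c(-1, 1, 1, 1), 2)),
    "initial point of chain 1")
})

test_that("independence component leaves the target distribution invariant", {
  # mixture kernel vs plain random walk on a shifted normal target
  target <- function(x) -0.5 * sum((x - 2)^2)
  prop <- list(mean = c(2, 2), scale_chol = diag(2) * 1.1, df = 8)
  draws <- run_mcmc(target,
                    chain_config(n_chains = 3, n_iterations = 4000,
                                 burn_in = 500, seed = 9),
                    n_params = 2, indep_proposal = prop)
  for (p in draws$param_names) {
    x <- pooled_draws(draws, p)
    expect_lt(abs(mean(x) - 2), 0.05)
    expect_lt(abs(var(x) - 1), 0.1)
  }
})

test_that("draws round-trip through the columnar text container", {
  draws <- run_mcmc(function(x) -0.5 * sum(x^2),
                    chain_config(n_chains = 2, n_iterations = 60,
                                 burn_in = 10, seed = 3),
                    n_params = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  save_draws(draws, path)
  back <- load_draws(path)
  expect_equal(back$values, draws$values)
  expect_equal(back$param_names, draws$param_names)
  expect_equal(back$config$n_iterations, draws$config$n_iterations)
  expect_equal(back$config$seed, draws$config$seed)
})

test_that("laplace proposal finds the mode and curvature of a gaussian", {
  s <- c(0.5, 2)
  target <- function(x) -0.5 * sum((x - c(1, -1))^2 / s^2)
  lp <- laplace_proposal(target, c(0, 0), inflate = 1)
  expect_equal(lp$mean, c(1, -1), tolerance = 1e-4)
  expect_equal(diag(lp$scale_chol %*% t(lp$scale_chol)), s^2,
               tolerance = 1e-3)
})
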