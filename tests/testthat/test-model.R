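test_that("covariance construction matches diag(sigma) corr diag(sigma)", {
  expect_equal(build_covariance(rep(1, 4), diag(4)), diag(4))
  s2 <- build_covariance(c(2, 3), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(s2, matrix(c(4, 3, 3, 9), 2))
  # random valid inputs: correlation reconstruction inverts the map
  set.seed(1)
  for (i in 1:10) {
    sg <- runif(4, 0.5, 30)
    z <- matrix(rnorm(16), 4); cr <- cov2cor(crossprod(z) + diag(4))
    sig <- build_covariance(sg, cr)
    expect_equal(cov2cor(sig), cr, tolerance = 1e-12)
    expect_equal(sqrt(diag(sig)), sg, tolerance = 1e-12)
  }
  expect_error(build_covariance(c(1, 2, 3), diag(4)), "match")
})

test_that("LKJ log-density follows (eta-1) log det", {
  expect_equal(lkj_log_density(diag(4), eta = 2.5), 0)
  r <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(lkj_log_density(r, eta = 1), 0)
  r6 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(lkj_log_density(r6, eta = 3), 2 * log(1 - 0.6^2))
  expect_error(lkj_log_density(matrix(c(1, 2, 2, 1), 2), 1),
               "positive definite")
})

test_that("log-prior composes uniform and LKJ terms", {
  p <- model_params(rep(50, 4), rep(25, 4), diag(4))
  expect_equal(log_prior(p, prior_spec()), -4 * log(100) - 4 * log(50))
  p_out <- p; p_out$mu[2] <- -1
  expect_identical(log_prior(p_out, prior_spec()), -Inf)
  p_out2 <- p; p_out2$sigma[1] <- 51
  expect_identical(log_prior(p_out2, prior_spec()), -Inf)
  # eta = 2 adds exactly the LKJ term of the same correlation matrix
  cr <- matrix(0.4, 4, 4); diag(cr) <- 1
  pc <- model_params(rep(50, 4), rep(25, 4), cr)
  expect_equal(log_prior(pc, prior_spec(lkj_eta = 2)),
               log_prior(pc, prior_spec()) + lkj_log_density(cr, 2))
})

test_that("MVN log-likelihood matches the brute-force density", {
  p <- model_params(rep(50, 4), rep(1, 4), diag(4))
  one <- matrix(p$mu, 1)
  expect_equal(mvn_log_likelihood(one, p), -2 * log(2 * pi))
  ten <- one[rep(1, 10), ]
  expect_equal(mvn_log_likelihood(ten, p), -20 * log(2 * pi))
  # explicit quadratic-form oracle with matrix inverse
  set.seed(7)
  cr <- cov2cor(crossprod(matrix(rnorm(16), 4)) + diag(4))
  pr <- model_params(c(40, 30, 45, 35), c(8, 12, 10, 9), cr)
  dat <- matrix(runif(24, 10, 90), 6, 4)
  sig <- build_covariance(pr$sigma, pr$corr)
  oracle <- sum(apply(dat, 1, function(r) {
    -2 * log(2 * pi) - 0.5 * as.numeric(determinant(sig)$modulus) -
      0.5 * t(r - pr$mu) %*% solve(sig) %*% (r - pr$mu)
  }))
  expect_equal(mvn_log_likelihood(dat, pr), oracle, tolerance = 1e-10)
  expect_error(mvn_log_likelihood(dat[, 1:3], pr), "4 columns")
})

test_that("log-posterior adds prior and likelihood and propagates -Inf", {
  set.seed(3)
  dat <- matrix(runif(40, 20, 80), 10, 4)
  p <- model_params(rep(50, 4), rep(25, 4), diag(4))
  expect_equal(log_posterior(dat, p),
               log_prior(p) + mvn_log_likelihood(dat, p))
  p_bad <- p; p_bad$mu[1] <- 101
  expect_identical(log_posterior(dat, p_bad), -Inf)
  # differences across parameter values reduce to likelihood + LKJ terms
  pr2 <- prior_spec(lkj_eta = 2)
  cr <- matrix(0.3, 4, 4); diag(cr) <- 1
  pa <- model_params(c(45, 50, 55, 60), rep(20, 4), cr)
  pb <- model_params(rep(50, 4), rep(25, 4), diag(4))
  lhs <- log_posterior(dat, pa, pr2) - log_posterior(dat, pb, pr2)
  rhs <- mvn_log_likelihood(dat, pa) - mvn_log_likelihood(dat, pb) +
    lkj_log_density(cr, 2) - lkj_log_density(diag(4), 2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("prior mass integrates correctly in a 2x2 reduction", {
  # the uniform blocks are normalized and, at eta = 1, the unnormalized
  # LKJ factor is the constant 1 over r in (-1, 1): the integral of
  # exp(log-prior) over (mu1, sigma1, r) must equal the known LKJ mass 2
  n <- 60
  mus <- seq(0, 100, length.out = n + 1)[-1] - 50 / n
  sds <- seq(0, 50, length.out = n + 1)[-1] - 25 / n
  rs <- seq(-1, 1, length.out = n + 1)[-1] - 1 / n
  un_mu <- sum(dunif(mus, 0, 100) * (100 / n))
  un_sd <- sum(dunif(sds, 0, 50) * (50 / n))
  lkj_mass <- sum(vapply(rs, function(r)
    exp(lkj_log_density(matrix(c(1, r, r, 1), 2), eta = 1)),
    numeric(1)) * (2 / n))
  expect_equal(un_mu * un_sd * lkj_mass, 2, tolerance = 0.01)
})
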