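test_that("EAP and posterior SD follow their conventions", {
  expect_equal(eap(c(1, 2, 3)), 2)
  expect_equal(eap(rep(7.5, 50)), 7.5)
  expect_error(eap(numeric(0)), "non-empty")
  expect_equal(posterior_sd(rep(3, 10)), 0)
  expect_equal(posterior_sd(c(0, 2)), sqrt(2))   # sample (n-1) convention
  expect_error(posterior_sd(1), "at least 2")
  set.seed(2)
  expect_equal(posterior_sd(rnorm(2e5, 0, 3)), 3, tolerance = 0.02)
})

test_that("HDI is the shortest window with lowest-endpoint tie-break", {
  expect_equal(unname(hdi(1:100, 0.95)), c(1, 95))
  expect_equal(unname(hdi(rep(4.2, 30))), c(4.2, 4.2))
  set.seed(3)
  x <- rnorm(1e5)
  h <- hdi(x, 0.95)
  expect_lt(abs(h[[1]] + 1.96), 0.05)
  expect_lt(abs(h[[2]] - 1.96), 0.05)
  expect_error(hdi(1:10), "at least 20")
  expect_error(hdi(1:100, 1.2), "mass")
})

test_that("HDI is never wider than the equal-tailed interval", {
  set.seed(4)
  for (i in 1:10) {
    x <- rgamma(5000, shape = sample(1:5, 1))   # skewed posteriors
    h <- hdi(x, 0.9)
    ci <- quantile(x, c(0.05, 0.95))
    expect_lte(h[[2]] - h[[1]], ci[[2]] - ci[[1]] + 1e-12)
  }
})

test_that("directional probability counts strict draw-wise exceedances", {
  expect_equal(directional_probability(2:6, 1:5), 1)
  expect_equal(directional_probability(1:5, 1:5), 0)   # ties are failures
  expect_equal(directional_probability(c(1, 3, 2), c(2, 1, 1)), 2 / 3)
  expect_error(directional_probability(1:4, 1:5), "equal length")
})

test_that("probability matrix has zero diagonal and complementary entries", {
  set.seed(6)
  m <- matrix(rnorm(4000 * 4, mean = c(2, 0, 1, -1)[col(matrix(0, 4000, 4))]),
              4000, 4)
  pm <- probability_matrix(m)
  expect_equal(diag(pm), setNames(rep(0, 4), shape_levels()))
  for (i in 1:4) for (j in 1:4) if (i != j)
    expect_equal(pm[i, j] + pm[j, i], 1)   # tie-free continuous draws
  # identical draw vectors: everything ties to zero
  same <- matrix(rep(rnorm(100), 4), 100, 4)
  expect_true(all(probability_matrix(same) == 0))
  # pooling order across chains does not change the entries
  v <- array(rnorm(3 * 500 * 4), c(3, 500, 4))
  d1 <- make_draws(v, paste0("mu", 1:4))
  d2 <- make_draws(v[c(2, 3, 1), , ], paste0("mu", 1:4))
  expect_equal(probability_matrix(boubataste:::mu_draw_matrix(d1)),
               probability_matrix(boubataste:::mu_draw_matrix(d2)))
})

test_that("joint compound probability respects draw-wise dependence", {
  set.seed(8)
  n <- 5000
  spec <- compound_spec(c(1, 3), c(2, 4))
  # group A uniformly above group B: certainty
  sure <- cbind(rnorm(n, 10), rnorm(n, -10), rnorm(n, 10), rnorm(n, -10))
  expect_equal(joint_probability(sure, spec), 1)
  # a tied pair annihilates the product
  tied <- sure; tied[, 4] <- tied[, 1]
  expect_equal(joint_probability(tied, spec), 0)
  # iid columns: exact rank-symmetry oracle. P(both of {1,3} beat both of
  # {2,4}) = 2!2!/4! = 1/6, while the marginal product is (1/2)^4 = 1/16;
  # the gap is the posterior dependence the joint form respects
  iid <- matrix(rnorm(4 * n), n, 4)
  jp <- joint_probability(iid, spec)
  expect_lt(abs(jp - 1 / 6), 0.02)
  pm_iid <- probability_matrix(iid)
  mp <- marginal_product(pm_iid[1, 2], pm_iid[1, 4],
                         pm_iid[3, 2], pm_iid[3, 4])
  expect_lt(abs(mp - 1 / 16), 0.01)
  expect_gt(jp, mp)
  # event inclusion: joint never exceeds any marginal
  dep <- matrix(rnorm(4 * n), n, 4) + rnorm(n)   # shared component
  expect_lte(joint_probability(dep, spec),
             min(probability_matrix(dep)[1, 2], probability_matrix(dep)[1, 4],
                 probability_matrix(dep)[3, 2], probability_matrix(dep)[3, 4]))
  expect_error(compound_spec(c(1, 2), c(2, 3)), "disjoint")
})

test_that("marginal products reproduce the printed compound arithmetic", {
  expect_equal(round(marginal_product(0.956, 0.987, 0.987, 0.966), 3), 0.9)
  expect_equal(round(marginal_product(0.573, 0.851, 0.506, 0.794), 3), 0.196)
  expect_equal(marginal_product(1, 1, 1, 1), 1)
  expect_error(marginal_product(0.5, 0.5, 0.5, 1.2), "probabilities")
})

test_that("draw summaries report EAP, SD and HDI per parameter", {
  set.seed(10)
  v <- array(rnorm(2 * 3000 * 2, mean = rep(c(0, 5), each = 6000)),
             c(2, 3000, 2))
  s <- summarize_draws(make_draws(v, c("a", "b")))
  expect_equal(s$parameter, c("a", "b"))
  expect_equal(s$eap, c(0, 5), tolerance = 0.06)
  expect_equal(s$sd, c(1, 1), tolerance = 0.05)
  expect_true(all(s$hdi_lower < s$eap & s$eap < s$hdi_upper))
})
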