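test_that("empirical prior is the Gaussian fit to the rating distribution", {
  # mean 5; population variance (9+1+1+9)/4 = 5 -> precision 0.2
  pr <- fit_prior(c(2, 4, 6, 8))
  expect_equal(pr$mu_prior, 5)
  expect_equal(pr$lambda_prior, 0.2)

  zero <- fit_prior(c(2, 4, 6, 8), "zero")
  expect_equal(zero$mu_prior, 0)
  expect_equal(zero$lambda_prior, 0.2)

  flat <- fit_prior(c(2, 4, 6, 8), "flat", flat_lambda = 1e-6)
  expect_equal(flat$mu_prior, 5)
  expect_equal(flat$lambda_prior, 1e-6)
})

test_that("degenerate rating sets are rejected", {
  expect_error(fit_prior(c(5, 5, 5)), "degenerate")
  expect_error(fit_prior(7), "degenerate")
})

test_that("effective precision follows the variant mappings", {
  p <- model_params(beta_conf = 0.01)
  expect_equal(effective_precision(5, p, "updating"), 0.05)
  expect_equal(effective_precision(5, p, "sampling"), 0.05)

  pe <- model_params(beta_conf = 0.02, precision_variant = "equal_weight")
  # items with conf {1, 5}: everyone updated with the mean precision
  expect_equal(effective_precision(c(1, 5), pe, "updating", mean_conf = 3),
               c(0.06, 0.06))
  # sampling precision untouched by the variant
  expect_equal(effective_precision(c(1, 5), pe, "sampling"), c(0.02, 0.10))
  expect_error(effective_precision(3, pe, "updating"), "mean_conf")

  pb <- model_params(beta_conf = 0.01, beta_bias = 0.02,
                     precision_variant = "biased")
  expect_equal(effective_precision(3, pb, "sampling"), 0.03)  # bias ignored
  expect_equal(effective_precision(3, pb, "updating"), 0.05)

  under <- model_params(beta_conf = 0.01, beta_bias = -0.02,
                        precision_variant = "biased")
  expect_error(effective_precision(1, under, "updating"), "non-positive")

  # missing confidence imputed with the default rating
  expect_equal(effective_precision(NA, p, "sampling"), 0.01 * 4.18)
})

test_that("value samples have the stated mean, variance and determinism", {
  expect_lt(abs(draw_sample(7, 1e12) - 7), 1e-4)
  set.seed(42); a <- draw_sample(rep(5, 10), 2)
  set.seed(42); b <- draw_sample(rep(5, 10), 2)
  expect_identical(a, b)
  set.seed(1)
  x <- draw_sample(rep(0, 1e5), 4)
  expect_lt(abs(var(x) / 0.25 - 1), 0.02)
  expect_error(draw_sample(5, -1), "invalid")
})

test_that("posterior updating matches the batch conjugate-normal form", {
  pr <- structure(list(mu_prior = 5, lambda_prior = 0.25, variant = "empirical"),
                  class = "prior_belief")
  st <- posterior_init(pr)
  expect_equal(st$mu, 5)
  expect_equal(st$lam, 0.25)
  expect_equal(st$n_samples, 0L)

  # four samples with mean 7 at tau = 1: lam = 4.25, mu = 5 + (4/4.25)*2
  for (x in c(6, 8, 7.5, 6.5)) st <- update_posterior(st, x, 1)
  expect_equal(st$lam, 4.25)
  expect_equal(st$mu, 5 + (4 / 4.25) * 2, tolerance = 1e-12)

  # flat-prior limit: posterior mean equals the sample mean
  fl <- posterior_init(fit_prior(c(2, 8), "flat"))
  for (x in rep(3.7, 10)) fl <- update_posterior(fl, x, 0.5)
  expect_lt(abs(fl$mu - 3.7), 1e-4)

  expect_error(update_posterior(st, 5, 0), "invalid")
})

test_that("iterated updates equal the closed form over random sequences", {
  set.seed(123)
  for (i in 1:50) {
    pr <- fit_prior(rnorm(30, 5, 2))
    tau <- runif(1, 0.005, 2)
    xs <- rnorm(sample(1:100, 1), runif(1, 0, 10), runif(1, 0.5, 4))
    st <- posterior_init(pr)
    for (x in xs) st <- update_posterior(st, x, tau)
    N <- length(xs)
    lam <- pr$lambda_prior + N * tau
    mu <- pr$mu_prior + (N * tau / lam) * (mean(xs) - pr$mu_prior)
    expect_equal(st$lam, lam, tolerance = 1e-10)
    expect_equal(st$mu, mu, tolerance = 1e-10)
    # precision bookkeeping is exact
    expect_equal(st$lam - pr$lambda_prior, N * tau)
  }
})

test_that("prior pull weakens monotonically with N and tau", {
  pr <- structure(list(mu_prior = 5, lambda_prior = 0.5, variant = "empirical"),
                  class = "prior_belief")
  pull <- function(N, tau) {
    lam <- pr$lambda_prior + N * tau
    abs((N * tau / lam) * (8 - pr$mu_prior))  # |mu - mu_prior| at xbar = 8
  }
  byN <- vapply(1:50, pull, numeric(1), tau = 0.1)
  expect_true(all(diff(byN) >= 0))
  bytau <- vapply(seq(0.01, 1, 0.01), function(t) pull(10, t), numeric(1))
  expect_true(all(diff(bytau) >= 0))
})

test_that("expected posterior mean shows the prior-bias pattern", {
  # at fixed N, E[mu] = mu_prior + w * (u_true - mu_prior), w = N tau / lam
  pr <- structure(list(mu_prior = 5, lambda_prior = 0.25, variant = "empirical"),
                  class = "prior_belief")
  tau <- 0.05; N <- 20; u <- 8
  set.seed(9)
  mus <- replicate(4000, {
    st <- posterior_init(pr)
    for (x in draw_sample(rep(u, N), tau)) st <- update_posterior(st, x, tau)
    st$mu
  })
  w <- N * tau / (pr$lambda_prior + N * tau)
  expected <- pr$mu_prior + w * (u - pr$mu_prior)
  se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - expected), 4 * se)
  # below-mean items are pulled up, above-mean items pulled down, in expectation
  expect_lt(expected, u)
})

test_that("decision rule picks the maximal estimate, ties at random", {
  expect_equal(decide(c(6.1, 5.9)), 1L)
  expect_equal(decide(c(0.0, 7.3)), 2L)
  set.seed(4)
  picks <- replicate(1e4, decide(c(4, 4)))
  expect_lt(abs(mean(picks == 1) - 0.5), 0.02)
})
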