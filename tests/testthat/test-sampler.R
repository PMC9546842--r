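test_that("variance full conditional matches direct inverse-gamma sampling", {
  set.seed(31)
  # q = 0: the full conditional is the prior IG(alpha/2, alpha*beta/2)
  a <- 6; b0 <- 1
  draws <- update_variance(numeric(0), c(a, b0), n_draws = 5000)
  oracle <- 1 / rgamma(5000, a / 2, rate = a * b0 / 2)
  expect_same_distribution(draws, oracle)

  # conjugacy algebra: alpha = beta = 0.001, u = (3, 4)
  # => IG(0.0005 + 1, 0.0000005 + 12.5)
  draws <- update_variance(c(3, 4), c(0.001, 0.001), n_draws = 10000)
  oracle <- 1 / rgamma(10000, 0.001 / 2 + 1, rate = 0.001 * 0.001 / 2 + 12.5)
  expect_same_distribution(draws, oracle)
  expect_true(all(draws > 0))
  expect_error(update_variance(1, c(-1, 1)), "positive")
})

test_that("gaussian block update reproduces its closed-form conditional", {
  set.seed(32)
  # flat-prior limit: X = I, prior var 1e8, sigma2_e = 1 => mean ~= l
  l <- c(1.7, -0.4, 2.2)
  draws <- t(replicate(4000, update_gaussian_block(l, diag(3), 1e8, 1)))
  expect_equal(colMeans(draws), l, tolerance = 0.08)
  expect_lt(max(abs(colMeans(draws) - l / (1 + 1e-8))), 0.08)

  # infinite-shrinkage limit: sigma2_block -> 0 collapses draws to 0
  draws0 <- replicate(200, update_gaussian_block(l, diag(3), 1e-12, 1))
  expect_lt(max(abs(draws0)), 1e-4)

  # 2-level toy incidence block vs the closed-form Gaussian conditional
  M <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1), ncol = 2)
  resid <- c(2, 2.5, -1, -0.5)
  s2b <- 0.5; s2e <- 0.25
  V <- solve(crossprod(M) / s2e + diag(2) / s2b)
  mu <- drop(V %*% crossprod(M, resid) / s2e)
  draws <- t(replicate(20000, update_gaussian_block(resid, M, s2b, s2e)))
  expect_equal(colMeans(draws), mu, tolerance = 0.02)
  expect_equal(cov(draws), V, tolerance = 0.05)
  # the fast incidence-block path targets the same conditional
  s <- drop(crossprod(M, resid))
  fast <- t(replicate(20000, latentcount:::update_incidence_block(
    s, colSums(M), s2b, s2e)))
  expect_same_distribution(draws[, 1], fast[, 1])
  expect_same_distribution(draws[, 2], fast[, 2])
})

test_that("latent Metropolis update preserves its target distribution", {
  set.seed(33)
  n <- 2000
  # weight 0: the family term drops and the invariant law is N(mu, sigma2_e)
  l <- rnorm(n, 5, 3)  # dispersed start
  for (i in 1:300) {
    l <- update_latent(rpois(n, 2), l, mu = rep(1, n), sigma2_e = 0.5,
                       step = 1, weight = 0)$l
  }
  expect_same_distribution(l, rnorm(n, 1, sqrt(0.5)))

  # y = 0 with a large-lambda start: stationary mean drops below mu
  set.seed(34)
  l <- rep(2, 500)
  keep <- numeric(0)
  for (i in 1:400) {
    l <- update_latent(rep(0L, 500), l, mu = rep(2, 500), sigma2_e = 1,
                       step = 1)$l
    if (i > 200) keep <- c(keep, mean(l))
  }
  # 1-D quadrature oracle for the posterior mean
  post <- function(x) exp(-exp(x)) * dnorm(x, 2, 1)
  m_oracle <- integrate(function(x) x * post(x), -15, 10)$value /
    integrate(post, -15, 10)$value
  expect_lt(mean(keep), 2)
  expect_equal(mean(keep), m_oracle, tolerance = 0.1)

  expect_error(update_latent(0L, 0, mu = NaN, sigma2_e = 1), "non-finite")
})

test_that("zero-layer updates follow their beta-binomial conjugacy", {
  set.seed(35)
  # zip with all positive counts: z forced to 0, pi ~ Beta(a, b + n)
  y <- rpois(40, 5) + 1L
  l <- rep(log(5), 40)
  out <- replicate(4000, {
    r <- update_zero_layer(y, l, pi = 0.3, pi_prior = c(2, 3), family = "zip")
    stopifnot(all(r$z == 0))
    r$pi
  })
  expect_same_distribution(out, rbeta(4000, 2, 3 + 40))

  # hurdle, 4 zeros / 6 positives, Beta(1,1) prior => Beta(5, 7)
  yh <- c(rep(0L, 4), rep(2L, 6))
  out <- replicate(4000, update_zero_layer(yh, rep(0, 10), pi = 0.5,
                                           pi_prior = c(1, 1),
                                           family = "hurdle")$pi)
  expect_same_distribution(out, rbeta(4000, 5, 7))

  # zip limit: y = 0 with huge lambda makes z = 1 almost surely
  r <- update_zero_layer(0L, l = 10, pi = 0.5, pi_prior = c(1, 1),
                         family = "zip")
  expect_equal(r$z, 1L)
  expect_error(update_zero_layer(y, l, pi = 0.5, pi_prior = c(1, 1),
                                 family = "poisson"), "zip and hurdle")
})

test_that("run_chain is deterministic and exposes the full-protocol default", {
  cfg_default <- sampler_config()
  expect_equal(cfg_default$iterations, 2000000L)
  expect_equal(cfg_default$burn_in, 100000L)
  expect_equal(cfg_default$thin, 10L)
  expect_equal(n_retained(cfg_default), 190000L)
  expect_error(sampler_config(iterations = 10, burn_in = 20), "smaller")

  sim <- scenario("corn-like", seed = 8, n_taxa = 3, n_replicates = 2)
  cfg <- quick_config(iterations = 600, burn_in = 200, thin = 2, seed = 99)
  r1 <- run_chain(sim$table, weak_spec(), cfg)
  r2 <- run_chain(sim$table, weak_spec(), cfg)
  expect_identical(r1$draws, r2$draws)
  expect_equal(nrow(r1$draws$b), n_retained(cfg))
  expect_gte(r1$acceptance_rate, 0)
  expect_lte(r1$acceptance_rate, 1)
})

test_that("normal-family posterior matches the conjugate linear-model oracle", {
  # no random effects + flat prior: posterior mean of b ~= OLS estimate
  set.seed(36)
  truth <- truth_record(b_true = c(20, 2, -1, 1, 3, -2, 2, -3),
                        sigma2_true = c(e = 4), family = "normal", seed = 21)
  sim <- simulate_dataset(2, 3, truth = truth)
  spec <- model_spec("normal", include_blocks = character(0),
                     hyper = list(e = c(0.001, 0.001)))
  cfg <- quick_config(iterations = 6000, burn_in = 1000, thin = 5, seed = 3)
  res <- run_chain(sim$table, spec, cfg)
  d <- build_design(sim$table, include_blocks = character(0))
  ols <- drop(solve(crossprod(d$X), crossprod(d$X, d$y)))
  pm <- colMeans(res$draws$b)
  mcse <- apply(res$draws$b, 2, sd) / sqrt(nrow(res$draws$b))
  expect_true(all(abs(pm - ols) < 4 * mcse))
  # flat-prior limit within 1e-3 relative error on the posterior mean formula
  ridge <- drop(solve(crossprod(d$X) +
                        diag(mean(res$draws$sigma2[, "e"]) / 1e8, ncol(d$X)),
                      crossprod(d$X, d$y)))
  expect_lt(max(abs(ridge - ols) / pmax(abs(ols), 1)), 1e-3)
})

test_that("joint-distribution (getting-it-right) moments match the prior", {
  # Geweke-style successive-conditional simulator on a 2-taxon toy:
  # cycling (y | l) -> one full parameter sweep leaves the joint prior
  # invariant, so chain moments must match exact prior moments.
  set.seed(37)
  a <- 6; b0 <- 1  # IG(3, 3): mean 1.5 (finite moments, unlike alpha=0.001)
  vb <- 0.5
  n_tax <- 2; n_obs <- 6
  tax <- rep(1:2, each = 3)
  cyc <- 6000
  s2u <- 1 / rgamma(1, a / 2, rate = a * b0 / 2)
  s2e <- 1 / rgamma(1, a / 2, rate = a * b0 / 2)
  b <- rnorm(1, 0, sqrt(vb))
  u <- rnorm(n_tax, 0, sqrt(s2u))
  l <- b + u[tax] + rnorm(n_obs, 0, sqrt(s2e))
  keep <- matrix(NA_real_, cyc, 3)
  M <- outer(tax, 1:2, "==") * 1
  for (it in seq_len(cyc)) {
    y <- rpois(n_obs, exp(l))
    for (rep_mh in 1:3)
      l <- update_latent(y, l, b + u[tax], s2e, step = 1.2)$l
    b <- update_gaussian_block(l - u[tax], matrix(1, n_obs, 1), vb, s2e)
    u <- update_gaussian_block(l - b, M, s2u, s2e)
    s2u <- update_variance(u, c(a, b0))
    e <- l - b - u[tax]
    s2e <- 1 / rgamma(1, a / 2 + n_obs / 2, rate = a * b0 / 2 + sum(e^2) / 2)
    keep[it, ] <- c(b, s2u, s2e)
  }
  keep <- keep[-(1:1000), ]
  # prior moments: E[b] = 0 (sd sqrt(.5)); E[sigma2] = (a b0/2)/(a/2 - 1) = 1.5
  ess <- function(x) length(x) / (1 + 2 * sum(acf(x, plot = FALSE,
                                                  lag.max = 50)$acf[-1]))
  for (j in 1:3) {
    m <- mean(keep[, j]); s <- sd(keep[, j]) / sqrt(max(ess(keep[, j]), 50))
    target <- c(0, 1.5, 1.5)[j]
    expect_lt(abs(m - target), 4 * s + 0.05)
  }
})

test_that("short hierarchical fits recover strong simulated signal", {
  truth <- truth_record(b_true = c(log(8), 0.8, rep(0, 6)),
                        sigma2_true = c(u1 = 1, e = 0.25), seed = 77)
  sim <- simulate_dataset(6, 3, truth = truth)
  res <- run_chain(sim$table, weak_spec(), quick_config(seed = 5))
  pm_b <- colMeans(res$draws$b)
  # the strong period-3 contrast is found with the right sign and size
  expect_equal(unname(pm_b["period_days3"]), 0.8, tolerance = 0.35)
  # error variance is recovered
  expect_equal(unname(mean(res$draws$sigma2[, "e"])), 0.25, tolerance = 0.12)
  # u1 variance posterior is in the right range for 6 taxa
  expect_gt(mean(res$draws$sigma2[, "u1"]), 0.2)
  # all-zero counts only warn
  tab0 <- sim$table; tab0$records$count <- 0L
  expect_warning(
    run_chain(tab0, weak_spec(),
              quick_config(iterations = 300, burn_in = 100, thin = 2)),
    "all counts are zero")
})

test_that("zip and hurdle chains run and recover the zero fraction", {
  sim <- scenario("zero-heavy", seed = 13, n_taxa = 4, n_replicates = 2)
  spec <- weak_spec("zip")
  res <- run_chain(sim$table, spec, quick_config(iterations = 3000,
                                                 burn_in = 1000, thin = 4,
                                                 seed = 2))
  expect_false(is.null(res$draws$pi))
  expect_lt(abs(mean(res$draws$pi) - 0.4), 0.12)
  resh <- run_chain(sim$table, weak_spec("hurdle"),
                    quick_config(iterations = 2000, burn_in = 500, thin = 3,
                                 seed = 2))
  expect_true(all(resh$draws$pi > 0 & resh$draws$pi < 1))
})
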