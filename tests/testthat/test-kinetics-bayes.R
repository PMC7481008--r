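# Bayesian rate inference: sufficient statistics, Gamma posteriors under
# uniform/Jeffreys priors, credible intervals, Bayes-factor model
# comparison.

test_that("sufficient statistics sum event times and censored lengths", {
  s <- transition_stats(
    transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1)))
  expect_equal(s$n_observed, 1)
  expect_equal(s$theta, 1.466)

  s0 <- transition_stats(anchor_rep_censored(5))
  expect_equal(s0$n_observed, 0)
  expect_equal(s0$theta, 5)

  # additivity under concatenation
  d1 <- gen_transition_data(2, 30, 1, seed = 1)
  d2 <- gen_transition_data(1, 20, 1, seed = 2)
  both <- transition_data(c(d1$observed, d2$observed),
                          c(d1$event_time, d2$event_time),
                          c(d1$total_time, d2$total_time))
  expect_equal(transition_stats(both)$n_observed,
               transition_stats(d1)$n_observed + transition_stats(d2)$n_observed)
  expect_equal(transition_stats(both)$theta,
               transition_stats(d1)$theta + transition_stats(d2)$theta)
})

test_that("posterior moments follow the closed forms and normalise to 1", {
  # n = 0, theta = 1, uniform: mean 1, variance 1
  p0 <- rate_posterior(anchor_rep_censored(1), "uniform")
  expect_equal(posterior_mean(p0), 1)
  expect_equal(posterior_var(p0), 1)

  # n = 1, theta = 1.466: mean 2/1.466
  d <- transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1))
  expect_equal(posterior_mean(rate_posterior(d, "uniform")), 2 / 1.466)

  # grid of (n, theta): (n+1)/theta, n/theta closed forms, integral = 1
  for (n in c(1, 5, 10, 100, 1000)) {
    for (theta in c(0.5, 3, 40)) {
      d <- transition_data(c(rep(TRUE, n), FALSE),
                           c(rep(theta / (n + 1), n), NA),
                           c(rep(theta, n + 1)))
      s <- transition_stats(d)
      pu <- rate_posterior(d, "uniform")
      pj <- rate_posterior(d, "jeffreys")
      expect_equal(posterior_mean(pu), (n + 1) / s$theta)
      expect_equal(posterior_var(pu), (n + 1) / s$theta^2)
      expect_equal(posterior_mean(pj), n / s$theta)
      expect_equal(posterior_var(pj), n / s$theta^2)
      for (p in list(pu, pj)) {
        expect_lt(abs(posterior_mass(p) - 1), 1e-8)
      }
    }
  }
})

test_that("Jeffreys prior requires an observed transition", {
  expect_error(rate_posterior(anchor_rep_censored(3), "jeffreys"),
               "at least one barrier crossing",
               class = "mdinfer_jeffreys_error")
})

test_that("uniform and Jeffreys posteriors converge with growing evidence", {
  # means 1.1 vs 1.0 at n = 10, theta = 10
  d10 <- transition_data(rep(TRUE, 10), rep(1, 10), rep(1, 10))
  expect_equal(posterior_mean(rate_posterior(d10, "uniform")), 1.1)
  expect_equal(posterior_mean(rate_posterior(d10, "jeffreys")), 1.0)

  # total-variation distance decreases monotonically in n at fixed k_true
  tv <- vapply(c(2, 5, 10, 25, 60, 150), function(n) {
    theta <- n / 2 # k_true = 2
    d <- transition_data(rep(TRUE, n), rep(theta / n, n), rep(theta, n))
    pu <- rate_posterior(d, "uniform")
    pj <- rate_posterior(d, "jeffreys")
    0.5 * integrate(function(k)
      abs(posterior_density(pu, k) - posterior_density(pj, k)),
      0, Inf, rel.tol = 1e-9)$value
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
})

test_that("credible intervals are exact Gamma quantiles and nest by level", {
  # n = 0, theta = 1: exponential quantiles [-ln 0.975, -ln 0.025]
  p0 <- rate_posterior(anchor_rep_censored(1), "uniform")
  ci <- credible_interval(p0, 0.95)
  expect_equal(ci$low, -log(0.975), tolerance = 1e-6)
  expect_equal(ci$high, -log(0.025), tolerance = 1e-6)

  ci99 <- credible_interval(p0, 0.99)
  expect_lt(ci99$low, ci$low)
  expect_gt(ci99$high, ci$high)

  # Gamma -> Normal limit at n = 100, theta = 100
  d <- transition_data(rep(TRUE, 100), rep(1, 100), rep(1, 100))
  p <- rate_posterior(d, "uniform")
  ci <- credible_interval(p, 0.95)
  m <- posterior_mean(p)
  hw <- 1.96 * sqrt(101) / 100
  expect_equal(ci$low, m - hw, tolerance = 0.02)
  expect_equal(ci$high, m + hw, tolerance = 0.02)

  # interval contains the mean; hpd is narrower than central for skewed n=1
  expect_true(ci$low < m && m < ci$high)
  p1 <- rate_posterior(anchor_a(), "uniform")
  hpd <- credible_interval(p1, 0.95, type = "hpd")
  cen <- credible_interval(p1, 0.95, type = "central")
  expect_lte(hpd$high - hpd$low, cen$high - cen$low)

  expect_error(credible_interval(p0, 1.2), class = "mdinfer_input_error")
})

test_that("Bayes factor is symmetric, log-space stable, and labelled", {
  bf <- bayes_factor(anchor_a(), anchor_b())
  expect_equal(bayes_factor(anchor_b(), anchor_a())$odds, bf$odds,
               tolerance = 1e-12)

  # large n: direct factorials would overflow, log-space must not
  big1 <- transition_data(rep(TRUE, 300), rep(0.5, 300), rep(1, 300))
  big2 <- transition_data(rep(TRUE, 300), rep(0.5, 300), rep(1, 300))
  bfb <- bayes_factor(big1, big2)
  expect_true(is.finite(bfb$odds))
  expect_lt(bfb$odds, 1) # identical samples favour one process

  # n = 20, theta = 20 each: odds < 1
  d20 <- transition_data(rep(TRUE, 20), rep(1, 20), rep(1, 20))
  expect_lt(bayes_factor(d20, d20)$odds, 1)

  expect_error(bayes_factor(anchor_rep_censored(2), anchor_rep_censored(2)),
               class = "mdinfer_input_error")
})

test_that("interpretation scale maps odds to the three verbal labels", {
  expect_equal(interpret_bayes_factor(0.26),
               "substantial evidence for one process")
  expect_equal(interpret_bayes_factor(1.0), "barely worth mentioning")
  expect_equal(interpret_bayes_factor(8.3),
               "substantial evidence for two processes")
  expect_error(interpret_bayes_factor(-1), class = "mdinfer_input_error")
})

test_that("tidiers expose posterior and Bayes-factor summaries", {
  td <- tidy(rate_posterior(anchor_a(), "uniform"))
  expect_true(all(c("mean", "variance", "low", "high") %in% names(td)))
  tb <- tidy(bayes_factor(anchor_a(), anchor_b()))
  expect_equal(tb$n_pooled, 1)
  expect_equal(tb$theta_pooled, 1.466)
})
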