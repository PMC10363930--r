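test_that("reference posteriors carry the prior mean and the right variance", {
  prior <- we_prior(0.6)
  h <- hypothetical_posterior(prior, 151)
  expect_equal(h$mean, -log(0.75))
  # equals the variance the usual update actually achieves
  expect_equal(h$variance,
               update_pair(prior, 0, 151)$covariance[1, 1],
               tolerance = 1e-14)
  expect_equal(h$variance, 0.053402, tolerance = 1e-5)

  # rho = 0: no variance reduction at all
  expect_equal(hypothetical_posterior(we_prior(0), 151)$variance, 0.08)

  l <- limiting_posterior(prior)
  expect_equal(l$mean, -log(0.75))
  expect_equal(l$variance, 0.08 * (1 - 0.36), tolerance = 1e-14)
  expect_equal(limiting_posterior(we_prior(0))$variance, 0.08)
  expect_equal(limiting_posterior(pair_belief(0, 0, 0.2, 0.2,
                                              0.8))$variance,
               0.2 * 0.36, tolerance = 1e-14)

  # hypothetical -> limiting as the observed study grows
  expect_equal(hypothetical_posterior(prior, 1e12)$variance, l$variance,
               tolerance = 1e-9)
})

test_that("quartile intervals are the central 50% of the normal", {
  q <- quartile_interval(0, 1)
  expect_equal(q$lower, qnorm(0.25), tolerance = 1e-12)
  expect_equal(q$upper, qnorm(0.75), tolerance = 1e-12)
  q2 <- quartile_interval(0.341977, 0.053402)
  expect_equal(c(q2$lower, q2$upper),
               0.341977 + c(-1, 1) * qnorm(0.75) * sqrt(0.053402),
               tolerance = 1e-12)
  expect_equal(c(q2$lower, q2$upper), c(0.186111, 0.497843),
               tolerance = 1e-5)
  # shift equivariance
  d <- 0.37
  q3 <- quartile_interval(0.341977 + d, 0.053402)
  expect_equal(q3$lower, q2$lower + d, tolerance = 1e-12)
  # zero variance degenerates to a point
  q0 <- quartile_interval(0.3, 0)
  expect_identical(c(q0$lower, q0$upper), c(0.3, 0.3))
})

test_that("overlap probability matches a brute-force integration oracle", {
  # perfectly aligned reference -> p = 1
  expect_equal(overlap_probability(0.3, 0.05, quartile_interval(0.3, 0.05)),
               1, tolerance = 1e-12)
  # disjoint reference -> p = 0
  expect_equal(overlap_probability(0, 0.01, effect_interval(5, 6)), 0)

  # worked example against the hypothetical reference
  post <- update_belief(we_prior(0.6), we_outcome())
  m1 <- post$means[1]; v1 <- post$covariance[1, 1]
  h <- hypothetical_posterior(we_prior(0.6), 151)
  p <- overlap_probability(m1, v1, quartile_interval(h$mean, h$variance))
  expect_equal(p, overlap_oracle(m1, v1, h$mean, h$variance),
               tolerance = 1e-6)
  expect_equal(p, 0.8397, tolerance = 1e-4)

  # random instances against the oracle
  set.seed(13)
  for (i in 1:50) {
    pm <- rnorm(1); pv <- runif(1, 0.01, 1)
    rm <- rnorm(1); rv <- runif(1, 0.01, 1)
    expect_equal(overlap_probability(pm, pv, quartile_interval(rm, rv)),
                 overlap_oracle(pm, pv, rm, rv), tolerance = 1e-6)
  }
})

test_that("increasing the posterior shift never increases the overlap", {
  ref <- quartile_interval(0, 0.05)
  shifts <- seq(0, 2, by = 0.05)
  p <- vapply(shifts, function(d) overlap_probability(d, 0.04, ref),
              numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("weight updating follows the two-component posterior-odds form", {
  w <- update_weights(0.5, 0.5, 0.8398)
  expect_equal(unname(w$posterior_weights), c(0.160, 0.840),
               tolerance = 5e-4)
  expect_equal(sum(w$posterior_weights), 1, tolerance = 1e-14)
  # p = 0.5 leaves weights unchanged
  expect_equal(unname(update_weights(0.5, 0.5, 0.5)$posterior_weights),
               c(0.5, 0.5), tolerance = 1e-14)
  expect_equal(unname(update_weights(0.3, 0.7, 0.5)$posterior_weights),
               c(0.3, 0.7), tolerance = 1e-14)
  # p = 1: all weight on the correlated component
  expect_equal(unname(update_weights(0.3, 0.7, 1)$posterior_weights),
               c(0, 1))
  # undefined updates
  expect_error(update_weights(0, 1, 0), "undefined")
  expect_error(update_weights(1, 0, 1), "undefined")
  expect_error(update_weights(0.6, 0.6, 0.5), "sum to 1")
})

test_that("robust update reproduces the worked-example mixture", {
  prior <- we_prior(0.6)
  o <- we_outcome()
  hyp <- robust_update(prior, o$score, o$information, method = "hypothetical")
  expect_equal(unname(hyp$weights$posterior_weights), c(0.16, 0.84),
               tolerance = 5e-3)
  # uncorrelated component: unobserved margin protected, observed updated
  unc <- hyp$posterior$components[[1]]
  cor <- hyp$posterior$components[[2]]
  expect_equal(round(unc$means, 3), c(0.288, 0.378))
  expect_equal(round(diag(unc$covariance), 3), c(0.08, 0.006))
  expect_identical(unc$covariance[1, 2], 0)
  expect_equal(round(cor$means, 3), c(0.342, 0.378))
  expect_equal(round(diag(cor$covariance), 3), c(0.053, 0.006))

  lim <- robust_update(prior, o$score, o$information, method = "limiting")
  expect_equal(unname(lim$weights$posterior_weights), c(0.17, 0.83),
               tolerance = 5e-3)
  # the limiting reference puts more weight on the uncorrelated component
  expect_gte(lim$weights$posterior_weights[["w01"]],
             hyp$weights$posterior_weights[["w01"]])

  std <- robust_update(prior, o$score, o$information, method = "standard")
  expect_equal(unname(std$weights$posterior_weights), c(0.5, 0.5))
  expect_true(is.na(std$weights$p))
})

test_that("pairwise splitting handles n > 2 combinations", {
  S <- diag(rep(0.2, 3))
  S[1, 2] <- S[2, 1] <- 0.8 * 0.2
  S[1, 3] <- S[3, 1] <- 0.3 * 0.2
  # theta2-theta3 independent
  prior <- mvn_belief(c(0.2, 0.3, 0.4), S,
                      labels = c("AB", "AC", "AD"))
  o <- study_outcome(1, 0.5 * 125, 125)
  res <- robust_update_multi(prior, o, method = "hypothetical")
  expect_named(res, c("AC", "AD"))
  # distinct rho values give distinct overlap probabilities
  expect_false(isTRUE(all.equal(res$AC$weights$p, res$AD$weights$p)))

  # n = 2 reduces to the single bivariate robust update (pair reordered
  # unobserved-then-observed)
  p2 <- we_prior(0.6)
  o2 <- we_outcome()
  multi <- robust_update_multi(p2, o2, method = "hypothetical")
  single <- robust_update(p2, o2$score, o2$information,
                          method = "hypothetical")
  expect_length(multi, 1L)
  expect_equal(multi$modMARIANNE$weights$p, single$weights$p,
               tolerance = 1e-12)

  # a pair with rho = 0 still gets a weight update, and its two mixture
  # components coincide
  S0 <- diag(rep(0.2, 3))
  S0[1, 2] <- S0[2, 1] <- 0.8 * 0.2
  prior0 <- mvn_belief(c(0.2, 0.3, 0.4), S0)
  res0 <- robust_update_multi(prior0, o, method = "hypothetical")
  z <- res0$theta3
  expect_equal(z$posterior$components[[1]]$means,
               z$posterior$components[[2]]$means, tolerance = 1e-12)
  expect_true(z$weights$p >= 0 && z$weights$p <= 1)

  expect_error(robust_update_multi(mvn_belief(0.2, 0.2),
                                   study_outcome(1, 1, 1)), "dimension")
})
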