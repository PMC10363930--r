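test_that("replicate draws follow the score-statistic sampling model", {
  sc <- sim_scenario(n_reps = 100000L, seed = 21)
  z <- draw_replicates(sc)
  expect_length(z, 100000L)
  # mean theta2 * V2 = 62.5 within 3 standard errors
  expect_lt(abs(mean(z) - 62.5), 3 * sqrt(125 / 1e5))
  expect_lt(abs(sd(z) - sqrt(125)), 0.1)
  # seeded reproducibility and prefix consistency
  expect_identical(z, draw_replicates(sc))
  sc_small <- sim_scenario(n_reps = 50L, seed = 21)
  expect_identical(z[1:50], draw_replicates(sc_small))
  # invalid scenarios rejected at construction
  expect_error(sim_scenario(v_obs = 0), "positive")
  expect_error(sim_scenario(rho = 1), "rho")
  expect_error(sim_scenario(n_reps = 0), "n_reps")
})

test_that("a scaled-down run reproduces the reference operating characteristics", {
  res <- run_scenario(sim_scenario(n_reps = 1000L, seed = 17))
  s <- res$summary
  expect_identical(s$approach,
                   c("univariate", "multivariate", "standard_mixture",
                     "hypothetical", "limiting"))
  get <- function(a, col) s[s$approach == a, col]
  # reference values: univ 0.520, multiv 0.802 (99.6% go), std mixture 0.661
  expect_equal(get("univariate", "mean_pos"), 0.520, tolerance = 0.005)
  expect_equal(get("univariate", "pct_go"), 0)
  expect_equal(get("multivariate", "mean_pos"), 0.802, tolerance = 0.02)
  expect_equal(get("multivariate", "pct_go"), 99.6, tolerance = 1)
  expect_equal(get("standard_mixture", "mean_pos"), 0.661, tolerance = 0.02)
  expect_equal(get("hypothetical", "mean_pos"), 0.615, tolerance = 0.02)
  expect_equal(get("limiting", "mean_pos"), 0.610, tolerance = 0.02)
  expect_equal(get("hypothetical", "mean_omega01"), 0.623, tolerance = 0.05)
  expect_equal(get("limiting", "mean_omega01"), 0.639, tolerance = 0.05)
  # qualitative ordering for this scenario
  mp <- setNames(s$mean_pos, s$approach)
  expect_true(mp["multivariate"] > mp["standard_mixture"])
  expect_true(mp["standard_mixture"] > mp["hypothetical"])
  expect_true(mp["hypothetical"] >= mp["limiting"])
  expect_true(mp["limiting"] > mp["univariate"])
  # mixture approaches bounded by univariate and multivariate means
  expect_true(all(mp[c("standard_mixture", "hypothetical", "limiting")] >=
                    min(mp["univariate"], mp["multivariate"])))
  expect_true(all(mp[c("standard_mixture", "hypothetical", "limiting")] <=
                    max(mp["univariate"], mp["multivariate"])))
})

test_that("an optimistic prior on the observed arm depresses borrowed PoS", {
  # prior mean 0.8 on the observed effect overestimates the true 0.5, so
  # the borrowed posterior mean falls and the multivariate approach ends
  # below every other approach
  res <- run_scenario(sim_scenario(mu2 = 0.8, n_reps = 1000L, seed = 17))
  mp <- setNames(res$summary$mean_pos, res$summary$approach)
  expect_true(mp["multivariate"] < min(mp[c("univariate",
                                            "standard_mixture",
                                            "hypothetical", "limiting")]))
})

test_that("zero correlation makes every approach collapse to the prior margin", {
  res <- run_scenario(sim_scenario(rho = 0, n_reps = 200L, seed = 9),
                      keep_replicates = TRUE)
  reps <- res$replicates
  expect_equal(reps$pos_multivariate,
               rep(reps$pos_univariate[1], nrow(reps)), tolerance = 1e-12)
  expect_equal(reps$pos_standard_mixture, reps$pos_multivariate,
               tolerance = 1e-12)
})

test_that("per-replication detail is internally consistent", {
  sc <- sim_scenario(n_reps = 100L, seed = 4)
  res <- run_scenario(sc, keep_replicates = TRUE)
  reps <- res$replicates
  # mixture PoS is the weighted combination of its two component PoS values
  expect_equal(reps$pos_hypothetical,
               reps$omega01_hypothetical * reps$pos_univariate +
                 (1 - reps$omega01_hypothetical) * reps$pos_multivariate,
               tolerance = 1e-12)
  # replicate 1 recomputed by hand through the exported pieces
  prior <- pair_belief(sc$mu1, sc$mu2, sc$prior_var, sc$prior_var, sc$rho)
  post <- update_pair(prior, reps$z2[1], sc$v_obs)
  expect_equal(reps$pos_multivariate[1],
               assurance_closed_form(post$means[1], post$covariance[1, 1],
                                     sc$design)$pos, tolerance = 1e-12)
  ru <- robust_update(prior, reps$z2[1], sc$v_obs, method = "limiting")
  expect_equal(reps$omega01_limiting[1],
               ru$weights$posterior_weights[["w01"]], tolerance = 1e-12)
})

test_that("PoS traces against observed-study size behave as expected", {
  prior <- pair_belief(0.5, 0.5, 0.2, 0.2, 0.8)
  d <- planned_design(0.05, information = 125)
  grid <- c(1e-6, 0.5, 2, 5, 20, 50, 125, 500, 2000)
  tab <- pos_vs_sample_size(prior, fixed_effect_estimate = 0, grid, d)
  # vanishing information: everything at the prior (univariate) PoS
  expect_equal(tab$multivariate[1], tab$univariate[1], tolerance = 1e-4)
  expect_equal(tab$hypothetical[1], tab$univariate[1], tolerance = 1e-4)
  # a null outcome with a positive prior mean: multivariate PoS strictly
  # decreasing in the observed information
  expect_true(all(diff(tab$multivariate) < 0))
  # robust approaches drift back to the univariate PoS for large studies
  gap <- abs(tab$hypothetical - tab$univariate)
  expect_lt(gap[length(grid)], 0.01)
  expect_lt(abs(tab$limiting[length(grid)] - tab$univariate[1]), 0.01)
  expect_gt(gap[3], gap[length(grid)])
  expect_error(pos_vs_sample_size(prior, 0, c(-1, 2), d), "positive")
})
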