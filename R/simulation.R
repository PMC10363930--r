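#' Replication-study scenario
#'
#' Configuration for the go/no-go operating-characteristics study: a
#' bivariate prior on the two combination effects, true effects generating
#' the observed study's score statistic, the observed study's information,
#' the planned future study's design, the go threshold, and mixture prior
#' weights for the robust approaches.
#'
#' Defaults are the reference study conditions: prior variance 0.2 for both
#' effects (a 20-patient normal-endpoint study worth of information),
#' borrowing correlation 0.8, both true effects 0.5, an observed study of
#' information 125 (500 patients, 1:1, unit variance), a planned study of the
#' same size tested two-sided at alpha 0.05, a go threshold of 0.6, 10,000
#' replications and equal mixture prior weights.
#'
#' @param mu1,mu2 prior means for the unobserved (A+B) and observed (A+C)
#'   combination effects.
#' @param prior_var common prior variance.
#' @param rho prior correlation (|rho| < 1).
#' @param theta_true length-2 vector of true effects; only the second
#'   generates data.
#' @param v_obs Fisher information of the observed study.
#' @param design a [planned_design()] for the future study.
#' @param threshold go threshold on the PoS.
#' @param n_reps number of replications (>= 1).
#' @param seed integer seed for the replicate draws.
#' @param w00,w10 mixture prior weights (uncorrelated, correlated).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(mu1 = 0.2, mu2 = 0.2, prior_var = 0.2, rho = 0.8,
                         theta_true = c(0.5, 0.5), v_obs = 125,
                         design = planned_design(alpha = 0.05,
                                                 information = 125),
                         threshold = 0.6, n_reps = 10000L, seed = 1L,
                         w00 = 0.5, w10 = 0.5) {
  if (!is.finite(prior_var) || prior_var <= 0)
    stop("prior_var must be strictly positive")
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (!is.finite(v_obs) || v_obs <= 0)
    stop("v_obs must be strictly positive")
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (length(theta_true) != 2L) stop("theta_true must have length 2")
  if (w00 < 0 || w10 < 0 || abs(w00 + w10 - 1) > 1e-9)
    stop("mixture prior weights must be nonnegative and sum to 1")
  stopifnot(inherits(design, "planned_design"))
  structure(list(mu1 = mu1, mu2 = mu2, prior_var = prior_var, rho = rho,
                 theta_true = as.numeric(theta_true), v_obs = v_obs,
                 design = design, threshold = threshold,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 w00 = w00, w10 = w10),
            class = "sim_scenario")
}

#' Draw replicate score statistics for a scenario
#'
#' Replicates of the observed study's score statistic,
#' \eqn{Z_2 \mid \theta_2 \sim N(\theta_2 V_2, V_2)}. Reproducible under the
#' scenario seed; the first k draws of a longer run equal a k-replication run
#' under the same seed.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional override of the scenario seed.
#' @return Numeric vector of `n_reps` score statistics.
#' @export
draw_replicates <- function(scenario, seed = scenario$seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  stats::rnorm(scenario$n_reps,
               mean = scenario$theta_true[2] * scenario$v_obs,
               sd = sqrt(scenario$v_obs))
}

#' Run a replication scenario under five analysis approaches
#'
#' For each replicate score statistic the PoS of the future study on the
#' unobserved combination is computed under:
#' \describe{
#'   \item{univariate}{assurance of the prior margin — constant, no
#'     borrowing.}
#'   \item{multivariate}{assurance of the [update_pair()] posterior margin.}
#'   \item{standard_mixture}{fixed-weight mixture of the uncorrelated and
#'     correlated component assurances.}
#'   \item{hypothetical, limiting}{mixture with weights updated from the
#'     truncated-posterior overlap against the corresponding reference.}
#' }
#' Go decisions use the strict rule PoS > threshold.
#'
#' @param scenario a [sim_scenario()].
#' @param keep_replicates keep the per-replication PoS/weight table?
#' @return An object of class `sim_result`: `summary` is a data frame with
#'   columns `approach`, `mean_pos`, `pct_go`, `mean_omega01`;
#'   `replicates` (if kept) holds the per-replication detail.
#' @examples
#' run_scenario(sim_scenario(n_reps = 200, seed = 7))
#' @export
run_scenario <- function(scenario, keep_replicates = FALSE) {
  sc <- scenario
  prior <- pair_belief(sc$mu1, sc$mu2, sc$prior_var, sc$prior_var, sc$rho)
  z2 <- draw_replicates(sc)
  pos_uni <- assurance_closed_form(sc$mu1, sc$prior_var, sc$design)$pos

  ref_h <- quartile_interval2(hypothetical_posterior(prior, sc$v_obs))
  ref_l <- quartile_interval2(limiting_posterior(prior))

  n <- sc$n_reps
  pos_mv <- numeric(n); pos_std <- numeric(n)
  pos_hyp <- numeric(n); pos_lim <- numeric(n)
  w01_hyp <- numeric(n); w01_lim <- numeric(n)
  for (r in seq_len(n)) {
    post <- update_pair(prior, z2[r], sc$v_obs)
    m1 <- post$means[1]
    v1 <- post$covariance[1, 1]
    pos_mv[r] <- assurance_closed_form(m1, v1, sc$design)$pos
    # theta1-margin of the uncorrelated component is the prior margin
    pos_std[r] <- sc$w00 * pos_uni + sc$w10 * pos_mv[r]
    p_h <- overlap_probability(m1, v1, ref_h)
    p_l <- overlap_probability(m1, v1, ref_l)
    wh <- update_weights(sc$w00, sc$w10, p_h, "hypothetical")$posterior_weights
    wl <- update_weights(sc$w00, sc$w10, p_l, "limiting")$posterior_weights
    w01_hyp[r] <- wh[["w01"]]; w01_lim[r] <- wl[["w01"]]
    pos_hyp[r] <- wh[["w01"]] * pos_uni + wh[["w11"]] * pos_mv[r]
    pos_lim[r] <- wl[["w01"]] * pos_uni + wl[["w11"]] * pos_mv[r]
  }

  pct <- function(pos) 100 * mean(pos > sc$threshold)
  summary <- data.frame(
    approach = c("univariate", "multivariate", "standard_mixture",
                 "hypothetical", "limiting"),
    mean_pos = c(pos_uni, mean(pos_mv), mean(pos_std),
                 mean(pos_hyp), mean(pos_lim)),
    pct_go = c(100 * (pos_uni > sc$threshold), pct(pos_mv), pct(pos_std),
               pct(pos_hyp), pct(pos_lim)),
    mean_omega01 = c(NA, NA, sc$w00, mean(w01_hyp), mean(w01_lim)),
    stringsAsFactors = FALSE)
  reps <- NULL
  if (keep_replicates)
    reps <- data.frame(rep = seq_len(n), z2 = z2,
                       pos_univariate = pos_uni, pos_multivariate = pos_mv,
                       pos_standard_mixture = pos_std,
                       pos_hypothetical = pos_hyp, pos_limiting = pos_lim,
                       omega01_hypothetical = w01_hyp,
                       omega01_limiting = w01_lim)
  structure(list(summary = summary, replicates = reps, scenario = sc),
            class = "sim_result")
}

# quartile interval from a list(mean, variance) reference
quartile_interval2 <- function(ref) quartile_interval(ref$mean, ref$variance)

#' @export
print.sim_result <- function(x, ...) {
  cat("Replication study:", x$scenario$n_reps, "replications, seed",
      x$scenario$seed, "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' PoS against the observed study's information for a fixed outcome
#'
#' Holds the observed effect estimate fixed (so \eqn{z_2 = \hat\theta V_2})
#' and traces the future-study PoS over a grid of observed-study information
#' values, under the univariate, multivariate, hypothetical and limiting
#' approaches. With a null fixed estimate and a positive prior mean the
#' multivariate PoS decreases in the information, while the robust approaches
#' drift back towards the univariate value as the implied shift grows.
#'
#' @param pair_prior a 2-dimensional [mvn_belief()].
#' @param fixed_effect_estimate the fixed value of \eqn{Z_2 / V_2}.
#' @param v_grid strictly positive information values.
#' @param design a [planned_design()].
#' @param w00,w10 mixture prior weights.
#' @return A data frame with columns `v2`, `univariate`, `multivariate`,
#'   `hypothetical`, `limiting`.
#' @export
pos_vs_sample_size <- function(pair_prior, fixed_effect_estimate, v_grid,
                               design, w00 = 0.5, w10 = 0.5) {
  validate_belief(pair_prior)
  if (any(!is.finite(v_grid)) || any(v_grid <= 0))
    stop("v_grid must be strictly positive")
  pos_uni <- assurance_closed_form(pair_prior$means[1],
                                   pair_prior$covariance[1, 1], design)$pos
  one <- function(v2) {
    z2 <- fixed_effect_estimate * v2
    post <- update_pair(pair_prior, z2, v2)
    pos_mv <- assurance_closed_form(post$means[1],
                                    post$covariance[1, 1], design)$pos
    mixpos <- function(method) {
      ru <- robust_update(pair_prior, z2, v2, w00, w10, method)
      w <- ru$posterior$weights
      margins <- vapply(ru$posterior$components, function(b)
        c(b$means[1], b$covariance[1, 1]), numeric(2))
      assurance_mixture(w, margins[1, ], margins[2, ], design)$pos
    }
    c(univariate = pos_uni, multivariate = pos_mv,
      hypothetical = mixpos("hypothetical"),
      limiting = mixpos("limiting"))
  }
  res <- t(vapply(v_grid, one, numeric(4)))
  data.frame(v2 = v_grid, res)
}
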