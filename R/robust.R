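#' Hypothetical reference posterior for the unobserved effect
#'
#' Reference distribution used to judge how far borrowing has shifted the
#' unobserved effect: it keeps the prior mean \eqn{\mu_1} but takes the
#' variance the usual update would actually achieve given information
#' \eqn{V_2} on the related effect,
#' \eqn{\sigma_1^2 - V_2\rho^2\sigma_1^2\sigma_2^2/(1 + V_2\sigma_2^2)}.
#'
#' @param pair_prior a 2-dimensional [mvn_belief()]; the observation is on
#'   component 2.
#' @param v2 information of the observed study (> 0).
#' @return A list with elements `mean` and `variance`.
#' @export
hypothetical_posterior <- function(pair_prior, v2) {
  validate_belief(pair_prior)
  if (length(pair_prior$means) != 2L) stop("pair_prior must be 2-dimensional")
  if (!is.finite(v2) || v2 <= 0) stop("v2 must be strictly positive")
  s1 <- pair_prior$covariance[1, 1]
  s2 <- pair_prior$covariance[2, 2]
  off <- pair_prior$covariance[1, 2]
  list(mean = pair_prior$means[1],
       variance = s1 - v2 * off^2 / (1 + v2 * s2))
}

#' Limiting reference posterior for the unobserved effect
#'
#' The infinite-information limit of [hypothetical_posterior()]: prior mean
#' \eqn{\mu_1} and variance \eqn{\sigma_1^2(1 - \rho^2)}.
#'
#' @inheritParams hypothetical_posterior
#' @return A list with elements `mean` and `variance`.
#' @export
limiting_posterior <- function(pair_prior) {
  validate_belief(pair_prior)
  if (length(pair_prior$means) != 2L) stop("pair_prior must be 2-dimensional")
  s1 <- pair_prior$covariance[1, 1]
  s2 <- pair_prior$covariance[2, 2]
  rho2 <- pair_prior$covariance[1, 2]^2 / (s1 * s2)
  if (rho2 >= 1) stop("|rho| must be < 1")
  list(mean = pair_prior$means[1], variance = s1 * (1 - rho2))
}

#' Interquartile interval of a normal distribution
#'
#' Central 50% interval, `mean +/- qnorm(0.75) * sd`. With zero variance the
#' interval degenerates to the point `[mean, mean]`.
#'
#' @param mean,variance parameters of the normal distribution (variance >= 0).
#' @return An [effect_interval()].
#' @export
quartile_interval <- function(mean, variance) {
  if (!is.finite(variance) || variance < 0)
    stop("variance must be nonnegative")
  half <- stats::qnorm(0.75) * sqrt(variance)
  effect_interval(mean - half, mean + half)
}

#' Overlap probability of the truncated posterior with a reference interval
#'
#' The posterior for the unobserved effect is truncated at its own quartiles,
#' and `p` is the probability mass of that truncated distribution falling in
#' the reference distribution's interquartile interval. Because the
#' truncation is at the posterior's own quartiles the normalizing mass is
#' exactly 0.5. Perfect alignment gives p = 1; a disjoint reference gives 0.
#' The value is clamped to \[0, 1\] against CDF rounding at the boundaries.
#'
#' @param posterior_mean,posterior_variance marginal posterior of the
#'   unobserved effect (variance > 0).
#' @param reference an [effect_interval()] (or numeric `c(lower, upper)`),
#'   usually the quartiles of the hypothetical or limiting reference.
#' @return The overlap probability p in \[0, 1\].
#' @export
overlap_probability <- function(posterior_mean, posterior_variance,
                                reference) {
  if (!is.finite(posterior_variance) || posterior_variance <= 0)
    stop("posterior_variance must be strictly positive")
  if (is.numeric(reference) && length(reference) == 2L)
    reference <- effect_interval(reference[1], reference[2])
  if (!inherits(reference, "effect_interval"))
    stop("reference must be an effect_interval or c(lower, upper)")
  own <- quartile_interval(posterior_mean, posterior_variance)
  lo <- max(own$lower, reference$lower)
  hi <- min(own$upper, reference$upper)
  if (lo >= hi) return(0)
  s <- sqrt(posterior_variance)
  mass <- stats::pnorm((hi - posterior_mean) / s) -
    stats::pnorm((lo - posterior_mean) / s)
  min(max(mass / 0.5, 0), 1)
}

#' Mixture-weight update from the overlap probability
#'
#' Posterior weights on the uncorrelated and correlated components:
#' \deqn{\omega_{01} = \frac{(1-p)\,\omega_{00}}{(1-p)\,\omega_{00} + p\,\omega_{10}},
#'   \qquad \omega_{11} = \frac{p\,\omega_{10}}{(1-p)\,\omega_{00} + p\,\omega_{10}}.}
#' With p = 0.5 the weights are unchanged; p near 1 moves weight to the
#' correlated component.
#'
#' @param w00,w10 prior weights on the uncorrelated and correlated
#'   components; nonnegative, summing to 1.
#' @param p overlap probability in \[0, 1\].
#' @param method label recorded in the result (`"hypothetical"`,
#'   `"limiting"` or `"standard"`).
#' @return An object of class `weight_update` with elements `p`,
#'   `prior_weights`, `posterior_weights`, `method`.
#' @export
update_weights <- function(w00, w10, p, method = "hypothetical") {
  if (w00 < 0 || w10 < 0 || abs(w00 + w10 - 1) > 1e-9)
    stop("prior weights must be nonnegative and sum to 1")
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  denom <- (1 - p) * w00 + p * w10
  if (denom == 0)
    stop("weight update undefined: (1-p)*w00 + p*w10 = 0")
  structure(list(p = p,
                 prior_weights = c(w00 = w00, w10 = w10),
                 posterior_weights = c(w01 = (1 - p) * w00 / denom,
                                       w11 = p * w10 / denom),
                 method = method),
            class = "weight_update")
}

#' @export
print.weight_update <- function(x, ...) {
  cat("Weight update (", x$method, "): p = ", format(x$p, digits = 4),
      "; (w00, w10) = (", paste(format(x$prior_weights, digits = 4),
                                collapse = ", "),
      ") -> (w01, w11) = (", paste(format(x$posterior_weights, digits = 4),
                                   collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Robust mixture update of a bivariate belief
#'
#' Updates the two-component mixture prior — uncorrelated
#' (\eqn{\rho = 0}) and correlated (the specified \eqn{\rho}) — from an
#' observation \eqn{(z_2, V_2)} on the second effect. Both components update
#' their observed margin; the uncorrelated component leaves the unobserved
#' margin at its prior. Weights update per `method`:
#' \describe{
#'   \item{standard}{weights unchanged.}
#'   \item{hypothetical}{p from [overlap_probability()] against the
#'     [hypothetical_posterior()] quartiles.}
#'   \item{limiting}{p against the [limiting_posterior()] quartiles.}
#' }
#'
#' @param pair_prior 2-dimensional [mvn_belief()] (the correlated prior).
#' @param z2,v2 score statistic and information of the observed study on
#'   component 2.
#' @param w00,w10 prior mixture weights (uncorrelated, correlated).
#' @param method `"hypothetical"`, `"limiting"` or `"standard"`.
#' @return A list with elements `posterior` (a [mixture_belief()], components
#'   ordered uncorrelated then correlated) and `weights` (a `weight_update`).
#' @examples
#' prior <- pair_belief(-log(0.75), -log(0.75), 0.08, 0.08, 0.6)
#' robust_update(prior, z2 = 58.235, v2 = 151, method = "hypothetical")
#' @export
robust_update <- function(pair_prior, z2, v2, w00 = 0.5, w10 = 0.5,
                          method = c("hypothetical", "limiting", "standard")) {
  method <- match.arg(method)
  validate_belief(pair_prior)
  if (length(pair_prior$means) != 2L) stop("pair_prior must be 2-dimensional")
  s1 <- pair_prior$covariance[1, 1]
  s2 <- pair_prior$covariance[2, 2]
  rho <- pair_prior$covariance[1, 2] / sqrt(s1 * s2)
  uncorr_prior <- pair_belief(pair_prior$means[1], pair_prior$means[2],
                              s1, s2, 0, labels = pair_prior$labels)
  post_uncorr <- update_pair(uncorr_prior, z2, v2)
  post_corr <- update_pair(pair_prior, z2, v2)
  if (method == "standard") {
    wu <- structure(list(p = NA_real_,
                         prior_weights = c(w00 = w00, w10 = w10),
                         posterior_weights = c(w01 = w00, w11 = w10),
                         method = "standard"),
                    class = "weight_update")
  } else {
    ref <- if (method == "hypothetical")
      hypothetical_posterior(pair_prior, v2) else limiting_posterior(pair_prior)
    p <- overlap_probability(post_corr$means[1], post_corr$covariance[1, 1],
                             quartile_interval(ref$mean, ref$variance))
    wu <- update_weights(w00, w10, p, method = method)
  }
  mix <- mixture_belief(unname(wu$posterior_weights),
                        list(post_uncorr, post_corr))
  list(posterior = mix, weights = wu)
}

#' Pairwise robust update for more than two combinations
#'
#' With n related combinations and one observed study, the joint problem is
#' split into n - 1 bivariate problems: the observed effect paired with each
#' unobserved effect in turn. Each pair gets its own overlap probability and
#' weight update; no joint n-dimensional mixture is reassembled — downstream
#' assurance for each unobserved combination uses its own pair's mixture
#' marginal.
#'
#' @param prior an n-dimensional [mvn_belief()], n >= 2.
#' @param outcome a [study_outcome()] on one component of `prior`.
#' @inheritParams robust_update
#' @return A named list, one element per unobserved component, each a
#'   [robust_update()] result (pair ordered unobserved-then-observed).
#' @export
robust_update_multi <- function(prior, outcome, w00 = 0.5, w10 = 0.5,
                                method = c("hypothetical", "limiting",
                                           "standard")) {
  method <- match.arg(method)
  validate_belief(prior)
  n <- length(prior$means)
  if (n < 2L) stop("prior must have dimension >= 2")
  i <- outcome$component
  if (i > n) stop("outcome component index exceeds belief dimension")
  labs <- if (is.null(prior$labels)) paste0("theta", seq_len(n)) else
    prior$labels
  out <- list()
  for (j in setdiff(seq_len(n), i)) {
    pp <- mvn_belief(prior$means[c(j, i)],
                     prior$covariance[c(j, i), c(j, i)],
                     labels = labs[c(j, i)])
    out[[labs[j]]] <- robust_update(pp, outcome$score, outcome$information,
                                    w00 = w00, w10 = w10, method = method)
  }
  out
}
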