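#' Conjugate posterior for a joint effect belief given study outcomes
#'
#' Updates an n-dimensional normal belief from the score statistics of one or
#' more simultaneously observed studies on distinct components. With selection
#' matrix A picking the observed components, diagonal information matrix V and
#' effect estimates \eqn{\hat\theta}, the posterior is
#' \deqn{\theta \mid \hat\theta \sim \mathrm{MVN}\big((\Sigma^{-1} + A^T V A)^{-1}
#'   (\Sigma^{-1}\mu + A^T V \hat\theta),\ (\Sigma^{-1} + A^T V A)^{-1}\big).}
#' The linear solves use a factorization rather than explicit inverses, and
#' the posterior covariance is symmetrized against floating-point drift.
#'
#' Simultaneous outcomes on the same component are rejected: the observation
#' information matrix is diagonal with one entry per observed component, and
#' such outcomes must be pooled before updating.
#'
#' @param prior an [mvn_belief()].
#' @param outcomes a single [study_outcome()] or a list of them with pairwise
#'   distinct `component` indices.
#' @return The posterior `mvn_belief`.
#' @examples
#' prior <- pair_belief(-log(0.75), -log(0.75), 0.08, 0.08, 0.6)
#' update_belief(prior, score_from_survival(0.68, 604, 1, component = 2))
#' @export
update_belief <- function(prior, outcomes) {
  validate_belief(prior)
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  if (length(outcomes) == 0L) return(prior)
  n <- length(prior$means)
  comp <- vapply(outcomes, `[[`, integer(1), "component")
  if (any(comp > n))
    stop("outcome component index exceeds belief dimension")
  if (anyDuplicated(comp))
    stop("duplicate components: pool simultaneous observations of one ",
         "effect before updating")
  m <- length(outcomes)
  A <- matrix(0, m, n)
  A[cbind(seq_len(m), comp)] <- 1
  V <- diag(vapply(outcomes, `[[`, numeric(1), "information"),
            nrow = m, ncol = m)
  theta_hat <- vapply(outcomes, effect_estimate, numeric(1))

  Sigma <- prior$covariance
  prec_prior <- tryCatch(chol2inv(chol(Sigma)), error = function(e)
    stop("prior covariance is singular; cannot update"))
  prec_post <- prec_prior + t(A) %*% V %*% A
  ch <- chol(prec_post)
  cov_post <- chol2inv(ch)
  cov_post <- (cov_post + t(cov_post)) / 2
  rhs <- prec_prior %*% prior$means + t(A) %*% (diag(V) * theta_hat)
  mean_post <- drop(cov_post %*% rhs)
  mvn_belief(mean_post, cov_post, labels = prior$labels)
}

#' Closed-form bivariate update from an outcome on the second component
#'
#' The two-combination special case of [update_belief()], written out in
#' closed form. With prior \eqn{(\mu_1,\mu_2)}, variances
#' \eqn{\sigma_1^2,\sigma_2^2}, correlation \eqn{\rho} and observation
#' \eqn{(z_2, V_2)} on the second effect, writing \eqn{k = 1 + V_2\sigma_2^2}:
#' \deqn{\mu_1' = \mu_1 + \frac{\rho\sigma_1\sigma_2}{k}(z_2 - V_2\mu_2),\quad
#'   \mu_2' = \frac{\mu_2 + \sigma_2^2 z_2}{k},}
#' \deqn{\sigma_1^{2\prime} = \sigma_1^2 - \frac{V_2\rho^2\sigma_1^2\sigma_2^2}{k},
#'   \quad \sigma_2^{2\prime} = \frac{\sigma_2^2}{k},\quad
#'   \mathrm{cov}' = \frac{\rho\sigma_1\sigma_2}{k}.}
#' The sign of \eqn{\rho} times the sign of \eqn{z_2/V_2 - \mu_2} gives the
#' direction in which the unobserved mean shifts.
#'
#' @param prior a 2-dimensional `mvn_belief`.
#' @param z2 observed score statistic on component 2.
#' @param v2 Fisher information of that observation (> 0).
#' @return The posterior `mvn_belief`.
#' @export
update_pair <- function(prior, z2, v2) {
  validate_belief(prior)
  if (length(prior$means) != 2L) stop("prior must be 2-dimensional")
  if (!is.finite(v2) || v2 <= 0) stop("v2 must be strictly positive")
  mu1 <- prior$means[1]; mu2 <- prior$means[2]
  s1 <- prior$covariance[1, 1]; s2 <- prior$covariance[2, 2]
  off <- prior$covariance[1, 2]      # rho * sigma1 * sigma2, exact
  k <- 1 + v2 * s2
  mean1 <- mu1 + off * (z2 - v2 * mu2) / k
  mean2 <- (mu2 + s2 * z2) / k
  var1 <- s1 - v2 * off^2 / k
  var2 <- s2 / k
  cov12 <- off / k
  mvn_belief(c(mean1, mean2),
             matrix(c(var1, cov12, cov12, var2), 2L, 2L),
             labels = prior$labels)
}

#' Sequential updating, one outcome at a time
#'
#' Applies [update_belief()] to each outcome in turn. By conjugacy this equals
#' the batch update for any ordering; it exists as a property surface (and as
#' a convenience when outcomes genuinely arrive over time).
#'
#' @inheritParams update_belief
#' @param outcomes ordered list of [study_outcome()] on distinct components.
#' @return The posterior `mvn_belief`.
#' @export
update_sequential <- function(prior, outcomes) {
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  comp <- vapply(outcomes, `[[`, integer(1), "component")
  if (anyDuplicated(comp))
    stop("duplicate components: pool simultaneous observations of one ",
         "effect before updating")
  post <- prior
  for (o in outcomes) post <- update_belief(post, o)
  post
}
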