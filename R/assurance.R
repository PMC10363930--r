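#' Closed-form assurance (probability of study success)
#'
#' Probability that the planned two-sided study rejects the null in favour of
#' the experimental arm, averaged over the current normal belief
#' \eqn{N(\mu, \sigma^2)} on the effect:
#' \deqn{\mathrm{PoS} = 1 - \Phi\!\left(\frac{V^{-1/2} z_{1-\alpha/2} - \mu}
#'   {\sqrt{V^{-1} + \sigma^2}}\right)}
#' where \eqn{V} is the planned study's Fisher information. Rejections in
#' favour of control do not count as success, so with a point belief at the
#' null the value is \eqn{\alpha/2}, not \eqn{\alpha}.
#'
#' @param mean,variance mean and variance (>= 0) of the belief on the effect.
#' @param design a [planned_design()].
#' @return An object of class `pos_result` with elements `pos` and `method`.
#' @examples
#' d <- planned_design(0.05, power = 0.8, target_effect = -log(0.75))
#' assurance_closed_form(-log(0.75), 0.08, d)  # 0.613
#' @export
assurance_closed_form <- function(mean, variance, design) {
  if (!is.finite(variance) || variance < 0)
    stop("variance must be nonnegative")
  v <- design$information
  zcrit <- stats::qnorm(1 - design$alpha / 2)
  pos <- 1 - stats::pnorm((zcrit / sqrt(v) - mean) / sqrt(1 / v + variance))
  structure(list(pos = pos, method = "closed_form"), class = "pos_result")
}

#' Monte-Carlo assurance by Bayesian clinical trial simulation
#'
#' Draws the true effect from the belief, draws the future estimate
#' \eqn{\hat\theta \sim N(\theta, V^{-1})}, and counts replicates with
#' \eqn{\hat\theta\sqrt{V} > z_{1-\alpha/2}}. Converges to
#' [assurance_closed_form()]; useful where no closed form exists (e.g.
#' success criteria beyond a single two-sided test).
#'
#' @inheritParams assurance_closed_form
#' @param n_draws number of simulated replicates (>= 1).
#' @param seed integer seed; defaults to 1 so unseeded runs are reproducible.
#' @return A `pos_result` with elements `pos`, `method`, `mc_draws`, `mc_seed`.
#' @export
assurance_monte_carlo <- function(mean, variance, design,
                                  n_draws = 10000L, seed = 1L) {
  if (!is.finite(variance) || variance < 0)
    stop("variance must be nonnegative")
  if (n_draws < 1) stop("n_draws must be >= 1")
  v <- design$information
  zcrit <- stats::qnorm(1 - design$alpha / 2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  theta <- stats::rnorm(n_draws, mean, sqrt(variance))
  theta_hat <- stats::rnorm(n_draws, theta, sqrt(1 / v))
  structure(list(pos = mean(theta_hat * sqrt(v) > zcrit),
                 method = "monte_carlo",
                 mc_draws = as.integer(n_draws), mc_seed = as.integer(seed)),
            class = "pos_result")
}

#' Assurance under a mixture belief
#'
#' The assurance integral is linear in the belief, so the mixture PoS is the
#' exact weighted sum of the per-component closed forms; it always lies
#' between the smallest and largest component values.
#'
#' @param weights nonnegative weights summing to 1.
#' @param means,variances per-component marginal means and variances for the
#'   effect of interest.
#' @param design a [planned_design()].
#' @return A `pos_result`.
#' @export
assurance_mixture <- function(weights, means, variances, design) {
  weights <- as.numeric(weights)
  if (length(weights) != length(means) || length(means) != length(variances))
    stop("weights, means and variances must have equal length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  comp <- mapply(function(m, v) assurance_closed_form(m, v, design)$pos,
                 means, variances)
  structure(list(pos = sum(weights * comp), method = "closed_form",
                 components = comp),
            class = "pos_result")
}

#' Go/no-go decision rule
#'
#' Go when the probability of success strictly exceeds the threshold.
#'
#' @param pos probability of success in \[0, 1\] (or a `pos_result`).
#' @param threshold decision threshold in \[0, 1\]; default 0.6.
#' @return `TRUE` (go) or `FALSE` (no-go).
#' @export
go_decision <- function(pos, threshold = 0.6) {
  if (inherits(pos, "pos_result")) pos <- pos$pos
  if (!is.finite(pos) || pos < 0 || pos > 1) stop("pos must lie in [0, 1]")
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  pos > threshold
}

#' @export
print.pos_result <- function(x, ...) {
  cat("Probability of success:", format(x$pos, digits = 4),
      paste0("(", x$method,
             if (identical(x$method, "monte_carlo"))
               paste0(", ", x$mc_draws, " draws, seed ", x$mc_seed), ")"),
      "\n")
  invisible(x)
}
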