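#' Score statistic and information from a survival trial summary
#'
#' Converts a reported hazard ratio, event count and allocation ratio into the
#' (Z, V) summary used for updating: \eqn{V \approx e R / (R+1)^2} and
#' \eqn{Z = -V \log(\mathrm{HR})}, so the implied effect estimate is
#' \eqn{-\log(\mathrm{HR})} (positive values favour the experimental arm).
#' The formula is symmetric in \eqn{R \leftrightarrow 1/R}, so either
#' orientation of the allocation ratio gives the same information.
#'
#' @param hazard_ratio observed hazard ratio, experimental vs control (> 0).
#' @param events total number of events (>= 1).
#' @param allocation_ratio allocation ratio R for R:1 randomisation (> 0).
#' @param component 1-based index of the combination this outcome refers to
#'   (used when the result updates a joint belief); default 1.
#' @return A [study_outcome()].
#' @examples
#' score_from_survival(0.68, 604, 1)  # V = 151, Z = 58.235
#' @export
score_from_survival <- function(hazard_ratio, events, allocation_ratio = 1,
                                component = 1L) {
  if (!is.finite(hazard_ratio) || hazard_ratio <= 0)
    stop("hazard_ratio must be strictly positive")
  if (!is.finite(events) || events < 1)
    stop("events must be a positive count")
  if (!is.finite(allocation_ratio) || allocation_ratio <= 0)
    stop("allocation_ratio must be strictly positive")
  v <- events * allocation_ratio / (allocation_ratio + 1)^2
  study_outcome(component, score = -v * log(hazard_ratio), information = v)
}

#' Planned-study information from alpha, power and a target effect
#'
#' Fisher information required for a two-sided test at level `alpha` to have
#' the stated power at the target effect:
#' \eqn{V = ((z_{1-\alpha/2} + z_{\mathrm{power}}) / \theta^*)^2}.
#' Quantiles are computed at full double precision.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param target_effect nonzero effect on the analysis scale, e.g. `-log` of
#'   the target hazard ratio.
#' @return The information V.
#' @examples
#' info_from_design(0.05, 0.8, -log(0.75))  # 94.838
#' @export
info_from_design <- function(alpha, power, target_effect) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  if (!is.finite(power) || power <= 0 || power >= 1)
    stop("power must lie strictly in (0, 1)")
  if (!is.finite(target_effect) || target_effect == 0)
    stop("target_effect must be nonzero")
  ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / target_effect)^2
}

#' Information of a two-arm normal-endpoint study
#'
#' For `n_total` patients randomised 1:1 with unit-variance normally
#' distributed responses, the information about the mean difference is
#' `n_total / 4` (so 500 patients give V = 125, and 20 give V = 5, i.e. a
#' posterior variance of 0.2 after an uninformative prior).
#'
#' @param n_total total sample size (>= 2).
#' @return The information V = n_total / 4.
#' @export
info_from_normal_endpoint <- function(n_total) {
  if (!is.finite(n_total) || n_total < 2)
    stop("n_total must be at least 2")
  n_total / 4
}

#' Effect estimate implied by a study outcome
#'
#' @param outcome a [study_outcome()].
#' @return The maximum-likelihood effect estimate \eqn{\hat\theta = Z / V}.
#' @export
effect_estimate <- function(outcome) {
  outcome$score / outcome$information
}
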