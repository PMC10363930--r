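#' Multivariate normal belief over related treatment effects
#'
#' Constructs and validates the joint normal belief over the effects of `n`
#' related combination therapies. Effects are stored on a scale where larger
#' values favour the experimental arm; for survival endpoints this is
#' \eqn{-\log(\mathrm{HR})}. The covariance carries the per-combination
#' variances \eqn{\sigma_i^2} on the diagonal and \eqn{\rho_{ij}\sigma_i\sigma_j}
#' off-diagonal, where \eqn{\rho_{ij}} is the prior level of borrowing between
#' combinations \eqn{i} and \eqn{j}.
#'
#' @param means numeric vector of effect means.
#' @param covariance symmetric positive semi-definite matrix (or a single
#'   variance for a univariate belief).
#' @param labels optional character vector of combination names.
#'
#' @return An object of class `mvn_belief` with elements `means`,
#'   `covariance` and `labels`.
#' @examples
#' mvn_belief(c(0.288, 0.288), matrix(c(0.08, 0.048, 0.048, 0.08), 2))
#' @export
mvn_belief <- function(means, covariance, labels = NULL) {
  means <- as.numeric(means)
  if (is.null(dim(covariance)))
    covariance <- matrix(as.numeric(covariance),
                         length(means), length(means))
  covariance <- as.matrix(covariance)
  b <- structure(list(means = means, covariance = covariance, labels = labels),
                 class = "mvn_belief")
  validate_belief(b)
}

#' Validate an mvn_belief
#'
#' Checks symmetry (to 1e-12), positive semi-definiteness (smallest eigenvalue
#' \eqn{\ge} -1e-10), strictly positive variances, implied correlations in
#' \eqn{[-1, 1]}, and dimension agreement. Returns the belief unchanged when
#' all invariants hold; otherwise stops with a message naming the violation.
#'
#' @param belief an `mvn_belief`.
#' @return `belief`, invisibly unchanged.
#' @export
validate_belief <- function(belief) {
  m <- belief$means
  S <- belief$covariance
  n <- length(m)
  if (!is.numeric(m) || n < 1L || anyNA(m) || any(!is.finite(m)))
    stop("means must be a finite numeric vector")
  if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
    stop("covariance dimensions (", nrow(S), "x", ncol(S),
         ") do not match length of means (", n, ")")
  if (anyNA(S) || any(!is.finite(S)))
    stop("covariance must be finite")
  if (max(abs(S - t(S))) > 1e-12)
    stop("covariance is not symmetric (max asymmetry ",
         format(max(abs(S - t(S)))), ")")
  d <- diag(S)
  if (any(d <= 0))
    stop("all variances (diagonal entries) must be strictly positive")
  sd_outer <- sqrt(outer(d, d))
  if (any(abs(S) > sd_outer + 1e-12))
    stop("off-diagonal entries imply a correlation with |rho| > 1")
  if (n > 1L) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("covariance is not positive semi-definite (smallest eigenvalue ",
           format(min(ev)), ")")
  }
  if (!is.null(belief$labels) && length(belief$labels) != n)
    stop("labels length does not match dimension")
  belief
}

#' Bivariate belief from means, variances and a correlation
#'
#' Convenience constructor for the two-combination case. The off-diagonal is
#' the exact product `rho * sqrt(var1 * var2)`, never a rounded display value:
#' downstream posterior quantities are sensitive to this at the third decimal.
#'
#' @param mu1,mu2 prior effect means.
#' @param var1,var2 strictly positive prior variances.
#' @param rho prior correlation, strictly inside (-1, 1).
#' @param labels optional length-2 character vector.
#' @return A 2-dimensional `mvn_belief`.
#' @examples
#' pair_belief(-log(0.75), -log(0.75), 0.08, 0.08, 0.6)
#' @export
pair_belief <- function(mu1, mu2, var1, var2, rho, labels = NULL) {
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("rho must satisfy |rho| < 1")
  if (var1 <= 0 || var2 <= 0)
    stop("variances must be strictly positive")
  off <- rho * sqrt(var1 * var2)
  mvn_belief(c(mu1, mu2),
             matrix(c(var1, off, off, var2), 2L, 2L),
             labels = labels)
}

#' Observed study outcome as a score statistic
#'
#' Summarises a completed study on one combination by its efficient score
#' statistic Z and Fisher information V; the implied effect estimate is
#' \eqn{\hat\theta = Z / V}, approximately \eqn{N(\theta, V^{-1})}.
#'
#' @param component 1-based index of the observed combination within the
#'   belief the outcome will update.
#' @param score score statistic Z.
#' @param information Fisher information V, strictly positive.
#' @return An object of class `study_outcome`.
#' @export
study_outcome <- function(component, score, information) {
  component <- as.integer(component)
  if (length(component) != 1L || is.na(component) || component < 1L)
    stop("component must be a single positive (1-based) index")
  if (!is.finite(information) || information <= 0)
    stop("information must be strictly positive")
  if (!is.finite(score / information))
    stop("effect estimate score/information must be finite")
  structure(list(component = component, score = as.numeric(score),
                 information = as.numeric(information)),
            class = "study_outcome")
}

#' Planned future study design
#'
#' Holds the two-sided significance level and the Fisher information of the
#' planned analysis. If `information` is omitted it is derived from
#' (`alpha`, `power`, `target_effect`) via [info_from_design()], and the
#' derivation is recorded in the `derived_from` element.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param information Fisher information of the planned analysis.
#' @param power,target_effect used to derive `information` when it is missing;
#'   `target_effect` is on the effect scale (e.g. `-log` of the target HR).
#' @return An object of class `planned_design`.
#' @examples
#' planned_design(alpha = 0.05, power = 0.8, target_effect = -log(0.75))
#' @export
planned_design <- function(alpha = 0.05, information = NULL,
                           power = NULL, target_effect = NULL) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  derived <- NULL
  if (is.null(information)) {
    if (is.null(power) || is.null(target_effect))
      stop("supply either information or both power and target_effect")
    information <- info_from_design(alpha, power, target_effect)
    derived <- list(alpha = alpha, power = power,
                    target_effect = target_effect)
  }
  if (!is.finite(information) || information <= 0)
    stop("information must be strictly positive")
  structure(list(alpha = alpha, information = as.numeric(information),
                 derived_from = derived),
            class = "planned_design")
}

#' Two-component mixture belief
#'
#' A weighted list of `mvn_belief` components of identical dimension; used for
#' the robust uncorrelated/correlated mixture where the weights are the
#' probabilities that the combinations are unrelated vs related.
#'
#' @param weights nonnegative weights summing to 1.
#' @param components list of `mvn_belief` objects of equal dimension.
#' @return An object of class `mixture_belief`.
#' @export
mixture_belief <- function(weights, components) {
  weights <- as.numeric(weights)
  if (length(weights) != length(components))
    stop("weights and components lengths differ")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be nonnegative and sum to 1")
  dims <- vapply(components, function(b) length(b$means), integer(1))
  if (length(unique(dims)) != 1L)
    stop("mixture components must share one dimension")
  lapply(components, validate_belief)
  structure(list(weights = weights, components = components),
            class = "mixture_belief")
}

#' Central interval on the effect scale
#'
#' @param lower,upper interval endpoints, `lower <= upper`.
#' @return An object of class `effect_interval`.
#' @export
effect_interval <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("need finite lower <= upper")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "effect_interval")
}

#' @export
print.mvn_belief <- function(x, ...) {
  n <- length(x$means)
  cat("MVN belief over", n, if (n == 1L) "effect\n" else "effects\n")
  lab <- if (is.null(x$labels)) paste0("theta", seq_len(n)) else x$labels
  cat("  means:  ", paste(lab, "=", format(x$means, digits = 4),
                          collapse = ", "), "\n")
  cat("  covariance:\n")
  m <- format(x$covariance, digits = 4)
  for (i in seq_len(n)) cat("   ", m[i, ], "\n")
  invisible(x)
}

#' @export
print.study_outcome <- function(x, ...) {
  cat("Study outcome: component ", x$component,
      "  Z = ", format(x$score, digits = 6),
      "  V = ", format(x$information, digits = 6),
      "  (effect estimate ", format(x$score / x$information, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' @export
print.planned_design <- function(x, ...) {
  cat("Planned design: alpha =", x$alpha,
      " information V =", format(x$information, digits = 6), "\n")
  if (!is.null(x$derived_from))
    cat("  derived from power =", x$derived_from$power,
        " target effect =", format(x$derived_from$target_effect, digits = 6),
        "\n")
  invisible(x)
}

#' @export
print.mixture_belief <- function(x, ...) {
  cat("Mixture belief with", length(x$weights), "components; weights:",
      paste(format(x$weights, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a belief to JSON
#'
#' Writes `{labels, means, variances, correlation}` with the correlation as a
#' full matrix (scalar for a bivariate belief). The inverse of
#' [belief_from_json()]; the round trip preserves full double precision.
#'
#' @param belief an `mvn_belief`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
belief_to_json <- function(belief, path = NULL) {
  v <- diag(belief$covariance)
  n <- length(v)
  R <- belief$covariance / sqrt(outer(v, v))
  corr <- if (n == 2L) R[1, 2] else R
  doc <- list(labels = belief$labels, means = belief$means,
              variances = v, correlation = corr)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a belief from JSON
#'
#' @param x a JSON string or a path to a JSON file containing
#'   `{labels, means, variances, correlation}` (correlation as a full matrix,
#'   or a single scalar for a bivariate belief).
#' @return An `mvn_belief`.
#' @export
belief_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  v <- as.numeric(doc$variances)
  n <- length(v)
  corr <- doc$correlation
  if (is.null(corr)) corr <- diag(n)
  if (length(corr) == 1L && n == 2L)
    corr <- matrix(c(1, corr, corr, 1), 2L, 2L)
  corr <- as.matrix(corr)
  S <- corr * sqrt(outer(v, v))
  lab <- doc$labels
  if (length(lab) == 0L) lab <- NULL
  mvn_belief(as.numeric(doc$means), S, labels = lab)
}
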