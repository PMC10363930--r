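#' Read a configuration file into validated objects
#'
#' Parses a YAML or JSON configuration describing any of: a prior belief, an
#' observed study outcome, a planned design, mixture weights, a go threshold,
#' and a replication scenario. Every object passes through the package
#' constructors, so all invariants are enforced at load time and violations
#' report the offending field.
#'
#' Recognised sections (all optional, but at least one must be present):
#' \describe{
#'   \item{prior}{`labels`, `means`, `variances`, `correlation` (full matrix
#'     or a single scalar for two combinations).}
#'   \item{outcome}{`component` (1-based) plus either `score` and
#'     `information`, or `hr`, `events` and optional `allocation_ratio`.}
#'   \item{design}{`alpha` plus either `information` or `power` with
#'     `target_effect` (or `target_hr`).}
#'   \item{weights}{`w00`, `w10`.}
#'   \item{threshold}{scalar go threshold.}
#'   \item{scenario}{fields of [sim_scenario()] (design given as above).}
#' }
#' Defaults follow the package conventions: alpha 0.05, threshold 0.6,
#' weights 0.5/0.5.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with the validated objects present in the file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || length(raw) == 0L)
    stop("config is empty or not a mapping")
  out <- list()
  if (!is.null(raw$prior)) out$prior <- config_prior(raw$prior)
  if (!is.null(raw$outcome)) out$outcome <- config_outcome(raw$outcome)
  if (!is.null(raw$design)) out$design <- config_design(raw$design)
  if (!is.null(raw$weights)) {
    w <- raw$weights
    if (is.null(w$w00) || is.null(w$w10))
      stop("weights: both w00 and w10 are required")
    if (w$w00 < 0 || w$w10 < 0 || abs(w$w00 + w$w10 - 1) > 1e-9)
      stop("weights: w00 and w10 must be nonnegative and sum to 1")
    out$weights <- c(w00 = w$w00, w10 = w$w10)
  }
  if (!is.null(raw$threshold)) {
    if (raw$threshold < 0 || raw$threshold > 1)
      stop("threshold: must lie in [0, 1]")
    out$threshold <- raw$threshold
  }
  if (!is.null(raw$scenario)) out$scenario <- config_scenario(raw$scenario)
  if (length(out) == 0L) stop("config contains no recognised section")
  out
}

config_prior <- function(p) {
  if (is.null(p$means) || is.null(p$variances))
    stop("prior: means and variances are required")
  v <- as.numeric(p$variances)
  n <- length(v)
  corr <- p$correlation
  if (is.null(corr)) corr <- diag(n)
  if (length(corr) == 1L) {
    if (n != 2L && corr != 0)
      stop("prior: scalar correlation only allowed for two combinations")
    corr <- diag(n) * (1 - corr) + corr
  }
  corr <- as.matrix(corr)
  lab <- p$labels
  if (length(lab) == 0L) lab <- NULL
  tryCatch(mvn_belief(as.numeric(p$means), corr * sqrt(outer(v, v)),
                      labels = lab),
           error = function(e) stop("prior: ", conditionMessage(e),
                                    call. = FALSE))
}

config_outcome <- function(o) {
  comp <- if (is.null(o$component)) 1L else o$component
  if (!is.null(o$score) && !is.null(o$information))
    return(study_outcome(comp, o$score, o$information))
  if (!is.null(o$hr) && !is.null(o$events)) {
    r <- if (is.null(o$allocation_ratio)) 1 else o$allocation_ratio
    return(score_from_survival(o$hr, o$events, r, component = comp))
  }
  stop("outcome: need either (score, information) or (hr, events)")
}

config_design <- function(d) {
  alpha <- if (is.null(d$alpha)) 0.05 else d$alpha
  if (!is.null(d$information))
    return(planned_design(alpha, information = d$information))
  eff <- d$target_effect
  if (is.null(eff) && !is.null(d$target_hr)) eff <- -log(d$target_hr)
  if (is.null(d$power) || is.null(eff))
    stop("design: need information, or power with target_effect/target_hr")
  planned_design(alpha, power = d$power, target_effect = eff)
}

config_scenario <- function(s) {
  design <- if (is.null(s$design))
    planned_design(alpha = 0.05, information = 125) else
      config_design(s$design)
  args <- s[intersect(names(s),
                      c("mu1", "mu2", "prior_var", "rho", "theta_true",
                        "v_obs", "threshold", "n_reps", "seed",
                        "w00", "w10"))]
  do.call(sim_scenario, c(args, list(design = design)))
}

#' Write results to CSV or JSON
#'
#' Simulation summaries go to CSV with stable columns
#' `(scenario_id, approach, mean_pos, pct_go, mean_omega01)`; any other
#' result (a `pos_result`, `mvn_belief`, `weight_update`, or plain list)
#' goes to JSON at full double precision, so numeric round trips are
#' lossless.
#'
#' @param results a `sim_result` (or list of them), or any JSON-serializable
#'   result object.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path,
                          format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    if (inherits(results, "sim_result")) results <- list(results)
    if (!all(vapply(results, inherits, logical(1), "sim_result")))
      stop("CSV output is for simulation results; use format = 'json'")
    ids <- names(results)
    if (is.null(ids)) ids <- seq_along(results)
    tab <- do.call(rbind, Map(function(id, r)
      cbind(scenario_id = id, r$summary), ids, results))
    ok <- tryCatch({
      suppressWarnings(utils::write.csv(tab, path, row.names = FALSE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("could not write to ", path)
  } else {
    out <- unclass_deep(results)
    ok <- tryCatch({
      jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("could not write to ", path)
  }
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
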