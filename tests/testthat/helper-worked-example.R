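# Shared fixtures: the pertuzumab combination worked example.
# Prior effect scale is -log(HR); both prior means target HR 0.75.

we_prior <- function(rho = 0.6, var = 0.08) {
  pair_belief(-log(0.75), -log(0.75), var, var, rho,
              labels = c("modMARIANNE", "CLEOPATRA"))
}

# observed study: HR 0.68 with 604 events, 1:1 -> Z = 58.235, V = 151
we_outcome <- function() score_from_survival(0.68, 604, 1, component = 2)

# planned study: alpha 0.05 two-sided, 80% power at target HR 0.75
we_design <- function() {
  planned_design(alpha = 0.05, power = 0.8, target_effect = -log(0.75))
}

# brute-force oracle for the truncated-posterior overlap probability:
# numeric integration of the posterior density over the intersection of the
# posterior's own interquartile interval with the reference's, divided by
# the integral over the posterior's interquartile interval.
overlap_oracle <- function(post_mean, post_var, ref_mean, ref_var) {
  s <- sqrt(post_var)
  own <- post_mean + c(-1, 1) * qnorm(0.75) * s
  ref <- ref_mean + c(-1, 1) * qnorm(0.75) * sqrt(ref_var)
  lo <- max(own[1], ref[1]); hi <- min(own[2], ref[2])
  if (lo >= hi) return(0)
  num <- integrate(dnorm, lo, hi, mean = post_mean, sd = s)$value
  den <- integrate(dnorm, own[1], own[2], mean = post_mean, sd = s)$value
  num / den
}
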