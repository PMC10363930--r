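# relassure

Probability of success (assurance) for a planned combination-therapy trial,
borrowing strength from the observed result of a *related* combination that
shares a backbone treatment.

## The problem and the model

Suppose combinations A+B and A+C share backbone A. A+C has read out; should
the sponsor run the phase III study of A+B? `relassure` models the two
treatment effects jointly,

    (theta_1, theta_2) ~ MVN(mu, Sigma),   Sigma_ij = rho_ij * sigma_i * sigma_j,

on a scale where larger is better (for survival, theta = -log HR). The
correlation `rho` is a design input — the amount of borrowing — not something
estimated from data. An observed study enters as its score statistic and
Fisher information (for survival, `V = e*R/(R+1)^2`, `Z = -V log HR`), and
conjugacy gives the joint posterior

    theta | theta_hat ~ MVN( (Sigma^-1 + A'VA)^-1 (Sigma^-1 mu + A'V theta_hat),
                             (Sigma^-1 + A'VA)^-1 ).

The probability of success of the planned study is the assurance of its
two-sided test under the updated margin,

    PoS = 1 - Phi( (V^-1/2 z_{1-alpha/2} - mu) / sqrt(V^-1 + sigma^2) ),

counting only rejections that favour the experimental arm. A robust
two-component mixture (uncorrelated vs correlated prior) reweights itself by
the overlap between the quartile-truncated posterior and a reference
distribution centred at the prior mean, so that a surprisingly large shift
automatically dials borrowing down. A replication engine quantifies go/no-go
operating characteristics of a `PoS > threshold` rule.

## Worked example

Prior means `-log(0.75)` with variances 0.08 and correlation 0.6 on both
effects; the related study observed HR 0.68 over 604 events (1:1); the
planned study is two-sided alpha 0.05, 80% power at target HR 0.75.

```r
library(relassure)

prior  <- pair_belief(-log(0.75), -log(0.75), 0.08, 0.08, 0.6,
                      labels = c("A+B", "A+C"))
obs    <- score_from_survival(0.68, 604, 1, component = 2)
obs
#> Study outcome: component 2  Z = 58.235  V = 151  (effect estimate 0.3857)

design <- planned_design(alpha = 0.05, power = 0.8,
                         target_effect = -log(0.75))
design$information
#> [1] 94.83793

assurance_closed_form(prior$means[1], 0.08, design)$pos   # before borrowing
#> [1] 0.6130231

post <- update_belief(prior, obs)
post$means
#> [1] 0.3419757 0.3781714
assurance_closed_form(post$means[1], post$covariance[1, 1], design)$pos
#> [1] 0.7110528

ru <- robust_update(prior, obs$score, obs$information, method = "hypothetical")
ru$weights
#> Weight update (hypothetical): p = 0.8397; (w00, w10) = (0.5, 0.5) -> (w01, w11) = (0.1603, 0.8397)

go_decision(0.711, threshold = 0.6)
#> [1] TRUE
```

Borrowing lifts the PoS of the planned study from 0.613 to 0.711 (0.669 at
rho 0.4, 0.777 at rho 0.8), and the robust weighting keeps 84% of the weight
on the correlated component because the observed shift is modest.

Operating characteristics of the go rule under repeated sampling:

```r
run_scenario(sim_scenario(n_reps = 10000, seed = 1))
#> Replication study: 10000 replications, seed 1
#>          approach mean_pos pct_go mean_omega01
#>        univariate   0.5216   0.00           NA
#>      multivariate   0.8027  99.54           NA
#>  standard_mixture   0.6621  95.60       0.5000
#>      hypothetical   0.6162  75.55       0.6194
#>          limiting   0.6117  72.10       0.6358
```

A command-line wrapper with `convert`, `update`, `pos`, `robust` and
`simulate` subcommands ships at `inst/cli/relassure.R`; see `?run_cli`.

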