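---
title: "Borrowing strength across related combination-therapy trials: the model behind relassure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Borrowing strength across related combination-therapy trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relassure)
```

## The problem

A sponsor holds a backbone therapy A and is weighing a phase III study of the
combination A+B. A related combination A+C — same backbone, different partner
— has already read out. Intuitively the A+C result should inform the decision
about A+B, but classical assurance calculations only use direct prior
information on A+B. `relassure` implements a joint-modelling framework in
which the two (or more) treatment effects are given a multivariate normal
prior whose correlation encodes how much the sponsor is willing to borrow,
the observed study updates the whole vector in closed form, and the planned
study's probability of success (PoS) is read off the updated margin.

## Model and updating

Effects live on a scale where larger is better; for a survival endpoint we
use $\theta = -\log(\mathrm{HR})$. The joint prior is
$\theta \sim \mathrm{MVN}(\mu, \Sigma)$ with
$\Sigma_{ii} = \sigma_i^2$ and $\Sigma_{ij} = \rho_{ij}\sigma_i\sigma_j$.
$\rho_{ij}$ is *not* estimated from data — with one observed study per
combination there is nothing to estimate it from — it is a design parameter:
the amount the unobserved mean should move per unit of surprise in the
related study.

An observed study enters as its efficient score statistic $Z$ and Fisher
information $V$, for which $\hat\theta = Z/V \mathrel{\dot\sim}
N(\theta, V^{-1})$ holds across many endpoint types. For survival,
$V \approx eR/(R+1)^2$ with $e$ events and $R{:}1$ allocation, and
$Z = -V\log(\mathrm{HR})$. With a selection matrix $A$ picking the observed
components and diagonal $V$, conjugacy gives

$$\theta \mid \hat\theta \sim \mathrm{MVN}\!\big((\Sigma^{-1} + A^TVA)^{-1}
(\Sigma^{-1}\mu + A^TV\hat\theta),\; (\Sigma^{-1} + A^TVA)^{-1}\big).$$

`update_belief()` implements this with Cholesky solves rather than explicit
inverses and symmetrizes the result; `update_pair()` is the bivariate closed
form, kept as an independent oracle — a property test asserts the two agree
to $10^{-10}$ on random instances, and `update_sequential()` checks
order-invariance of one-at-a-time updating.

## Assurance

The PoS of the planned study is the power averaged over the current belief.
For a two-sided test at level $\alpha$ with planned information $V$ and
belief $N(\mu, \sigma^2)$ on the effect,

$$\mathrm{PoS} = 1 - \Phi\!\left(\frac{V^{-1/2}z_{1-\alpha/2} - \mu}
{\sqrt{V^{-1} + \sigma^2}}\right),$$

counting only rejections in favour of the experimental arm — a point belief
at the null gives $\alpha/2$, not $\alpha$. `assurance_monte_carlo()`
estimates the same integral by simulating the future trial and exists for
success definitions without a closed form; for a mixture belief the
assurance is linear, so `assurance_mixture()` takes the exact weighted sum
of component closed forms rather than re-simulating. The published worked
example prints robustified PoS values about 0.006 below that exact weighted
sum of its own printed components; we compute the weighted sum, which is the
quantity the mixture model defines.

## Robust borrowing

If A+B and A+C turn out unrelated, borrowing hurts. The robust extension
places a two-component mixture prior on the pair: an uncorrelated component
($\rho = 0$) and the correlated component, with prior weights
$\omega_{00}, \omega_{10}$ (default 0.5/0.5 — agnostic between the two
hypotheses). Both components update conjugately (the uncorrelated one still
updates the *observed* margin; only the unobserved margin is protected). The
weights update through an overlap measure $p$: the posterior for the
unobserved effect, truncated at its own quartiles, is integrated over the
interquartile interval of a reference distribution centred at the prior mean
—

* **hypothetical** reference: variance the update actually achieved given
  the observed study's information;
* **limiting** reference: variance $\sigma_1^2(1-\rho^2)$, the
  infinite-information floor.

Because truncation is at the posterior's own quartiles the normalizing mass
is exactly 0.5, so $p = 1$ for perfect alignment, and $p$ is non-increasing
in the size of the mean shift. The posterior weights are
$\omega_{01} \propto (1-p)\,\omega_{00}$ and
$\omega_{11} \propto p\,\omega_{10}$; $p = 0.5$ leaves the weights
untouched. The update is undefined (and errors) in the two degenerate
corners $p=0,\omega_{00}=0$ and $p=1,\omega_{10}=0$. Note the limiting
reference is tighter than anything a finite study can achieve, so its $p$
is generally smaller and it puts somewhat more weight on the uncorrelated
component.

With more than two combinations, the problem is split into $n-1$ bivariate
problems, each pairing the observed effect with one unobserved effect and
carrying its own $p$ and weights. We deliberately do not reassemble a joint
$n$-dimensional mixture: downstream assurance for each combination uses its
own pair's mixture margin, and no joint recombination is defined by the
framework.

## Worked example

The shipped numbers come from the trastuzumab-backbone example: prior means
$-\log(0.75)$, variances 0.08, correlation 0.6; observed study HR 0.68 with
604 events ($Z = 58.235$, $V = 151$); planned study at two-sided
$\alpha = 0.05$, 80% power, target HR 0.75 ($V = 94.838$).

```{r worked-example}
prior <- pair_belief(-log(0.75), -log(0.75), 0.08, 0.08, 0.6,
                     labels = c("A+B", "A+C"))
obs <- score_from_survival(0.68, 604, 1, component = 2)
design <- planned_design(alpha = 0.05, power = 0.8,
                         target_effect = -log(0.75))
post <- update_belief(prior, obs)
post
assurance_closed_form(prior$means[1], 0.08, design)          # 0.613 prior
assurance_closed_form(post$means[1], post$covariance[1, 1],
                      design)                                 # 0.711 posterior
robust_update(prior, obs$score, obs$information,
              method = "hypothetical")$weights                # w01 = 0.16
```

A subtlety that matters: the off-diagonal of the prior covariance must be
the exact product $0.6 \times 0.08 = 0.048$. Using the two-decimal display
value 0.05 moves the posterior PoS visibly off 0.711, which is why
`pair_belief()` always forms the exact product.

## The replication engine and what it emulates

`sim_scenario()`/`run_scenario()` quantify operating characteristics of the
go/no-go rule (go when PoS strictly exceeds a threshold). Each replication
draws the observed study's score statistic from its sampling distribution
$Z_2 \mid \theta_2 \sim N(\theta_2 V_2, V_2)$ and evaluates the PoS under
five analysis strategies: univariate (no borrowing — constant across
replications), multivariate, fixed-weight mixture, and the two
weight-updating mixtures.

The default scenario is the reference configuration: prior means 0.2,
common prior variance 0.2 (the information content of a 20-patient
normal-endpoint study), borrowing correlation 0.8, both true effects 0.5,
an observed study of information 125 (500 patients, 1:1, unit variance), a
planned study of the same size at $\alpha = 0.05$, threshold 0.6, and
10,000 replications — which run in a couple of seconds since every
per-replication quantity is closed-form. The tests exercise a 1,000-
replication scaled version (Monte-Carlo error on the mean PoS well under
0.02) plus the full 10,000 for the headline reproduction.

The generator emulates the large-sample normal approximation to the score
statistic only. It does not simulate patient-level survival data, staggered
accrual, information mis-specification, or non-normal small-sample
behaviour — so passing tests demonstrate correctness of the updating and
weighting machinery under the stated model, not robustness of the normal
approximation itself on real trials.

## Numerical choices and edge cases

* Posterior solves use Cholesky factorization of the precision; the
  covariance is symmetrized by averaging with its transpose. A singular
  prior covariance is an error, as are simultaneous outcomes on the same
  component (pooling policy is the user's call, so we refuse to guess).
* Validation tolerances: symmetry $10^{-12}$, smallest eigenvalue
  $\ge -10^{-10}$ (slightly indefinite user-entered correlation matrices
  for $n > 2$ are rejected rather than repaired), weight sums $10^{-12}$.
* $p$ is clamped to $[0,1]$ after CDF evaluation; zero-variance beliefs are
  allowed in assurance (point mass) and produce degenerate quartile
  intervals.
* All randomness flows from a single integer seed. The only stochastic
  object in a scenario run is the replicate vector, drawn once under
  `set.seed(seed)`, so the first $k$ replicates of a longer run coincide
  with a $k$-replication run — partial reruns are comparable by
  construction. RNG state of the caller is restored afterwards.
* Quantiles are computed at full double precision throughout; reproducing
  the printed design information 94.838 fails with the 1.96 shortcut.

## Limitations

* $\rho$ is a judgment, not an estimate; the robust mixture softens but does
  not remove that dependence.
* Only one observed component at a time is supported in the robust pathway
  (the pairwise splitting above); the plain conjugate update accepts any
  number of simultaneously observed distinct components.
* Success is a single two-sided superiority test; interim analyses,
  non-inferiority margins and alternative PoS definitions are out of scope.
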