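---
title: "Simulating and analysing cross-sectional stepped wedge trials with binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing cross-sectional stepped wedge trials with binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepwedgesim)
```

## The design and the data-generating model

A cross-sectional stepped wedge cluster randomised trial (SW-CRT) with
$S$ steps observes $M$ clusters over $S + 1$ measurement periods
$j = 0, 1, \dots, S$. Every cluster starts in the control condition; at
each step a randomly chosen group of $M / S$ clusters crosses to the
intervention, so that by the final period all clusters are treated. New
subjects are sampled every period (no subject is measured twice), with
$n_{jk}$ subjects in the *cell* of cluster $k$ at period $j$.

`sw_simulate()` generates a binary outcome $Y_{ijk}$ in three stages:

1. **Cluster heterogeneity.** True baseline cluster proportions are drawn
   as $p_{0k} \sim \mathrm{Beta}(a, b)$, with $(a, b)$ solved in closed
   form (`solve_beta_params()`) so that $E[p_{0k}] = \mu$ and the
   intra-cluster correlation equals $\rho = 1/(a + b + 1)$:
   $a = \mu(1/\rho - 1)$, $b = (1 - \mu)(1/\rho - 1)$.
2. **Cell probabilities.** With $\beta_{0k} = \mathrm{logit}(p_{0k})$,
   treatment indicator $X_{jk}$ and period index $j$,
   $$p_{jk} = \mathrm{logit}^{-1}\!\big(\beta_{0k} + \beta_1 X_{jk} + \beta_2 j\big),$$
   where $e^{\beta_1}$ is the intervention odds ratio and $e^{\beta_2}$
   the per-period time odds ratio. The true time trend is linear on the
   log-odds scale by construction.
3. **Outcomes.** Cell event counts are drawn as
   $\mathrm{Binomial}(n_{jk}, p_{jk})$, which is exactly the sum of
   $n_{jk}$ independent Bernoulli subjects. Counts are stored per cell
   rather than per subject: subjects within a cell are exchangeable, so
   every analysis method below has identical likelihood or estimating
   equations on either representation, and the aggregated form makes the
   Monte-Carlo harness orders of magnitude faster.

A realisation with no events anywhere in the control condition, or none
anywhere in the intervention condition, is unanalysable by several of
the methods; such datasets are discarded and regenerated from a fresh
random substream. After 1000 consecutive discards the scenario is
declared degenerate and an error raised — under any reasonable setting
discards are rare, so hitting the cap signals a mis-specified
configuration.

### What the generator emulates, and what it does not

The generator reproduces the study conditions of the simulation
framework it implements: equal cluster sizes, equal cells, a
cross-sectional population (no subject-level serial correlation),
cluster heterogeneity that is beta-distributed (not logit-normal — so
the GLMM below is deliberately analysed under a mis-specified
random-effect distribution, as a practitioner would), and a log-linear
time trend. It does **not** emulate unequal cluster sizes, missing
data, cohort designs with within-subject correlation, autoregressive
within-cluster correlation, or non-linear time trends. Passing tests
therefore speak to method behaviour under these idealised conditions,
not to robustness against those departures.

## The four analysis methods

All four are available through one front end,
`sw_fit(trial, method, time_adjustment)`, and return a classed result
with `print()`, `summary()`, `coef()` and `as.data.frame()` methods.
The estimate of interest is always the intervention effect.

**Random-intercept logistic GLMM** (`"glmm"`).
$\mathrm{logit}\, E[Y_{jk}] = \beta_0 + a_{0k} + \beta_1 X_{jk} + \beta_2 j$
with $a_{0k} \sim N(0, \sigma^2)$. The marginal likelihood integrates
each cluster's contribution over its random intercept by *adaptive*
Gauss–Hermite quadrature with 4 nodes: nodes are centred at each
cluster's posterior mode and scaled by the posterior curvature, found
by a damped Newton iteration (the integrand is strictly log-concave).
Non-adaptive 4-node quadrature is demonstrably inaccurate for large
cells, which is why adaptivity is not optional. The optimiser is
L-BFGS-B over $(\beta, \log\sigma)$: the log scale enforces
$\sigma > 0$, and the explicit lower bound $\log\sigma \ge -10$ lets a
variance component that collapses to zero terminate cleanly at the
boundary instead of drifting along the flat profile (a fit ending below
$\log\sigma = -8$ is reported as a converged $\hat\sigma = 0$ fit, with
fixed effects equal to the pooled logistic fit — discarding such fits
would bias the Monte-Carlo summaries, since they are legitimate under
low ICC). Start values: pooled logistic fit for $\beta$,
$\sigma = 0.3$. Convergence: relative objective change below $10^{-8}$,
at most 200 iterations. Standard errors come from the numerically
differentiated observed information; the Wald statistic is referred to
a $t$ distribution with *containment* degrees of freedom
$N - \mathrm{rank}([X\;Z])$, where $N$ counts subjects, $X$ is the
fixed design and $Z$ the cluster-indicator design.

**Logistic GEE** (`"gee"`).
The population-average model
$\mathrm{logit}\, E[Y_{jk}] = \beta_0 + \beta_1 X_{jk} + \beta_2 j$
with an exchangeable working correlation among all subjects of a
cluster. The working correlation is re-estimated each iteration by the
moment estimator over within-cluster subject pairs (denominator
$\sum_k n_k(n_k-1)/2 - p$, scaled by the Pearson dispersion), and must
stay inside $(-1/(\max_k n_k - 1),\, 1)$. Because subjects within a
cell share a covariate row, all quantities reduce exactly to cell-level
sums via the Sherman–Morrison inverse of the exchangeable correlation
matrix; the fitter works on those closed forms and is verified in the
tests against an explicit subject-level matrix oracle and against an
independent GEE implementation. Two variance estimators are computed:
the Liang–Zeger robust sandwich (`se_robust`, the default basis of the
reported p-value, standard-normal reference) and the model-based
working-covariance estimate $\hat\phi B^{-1}$ (`se_model`,
`se_type = "model"`). With very few clusters the sandwich is biased
downward and its Wald test anti-conservative — see the reproduction
notes below. Because the GEE estimates a marginal
(population-average) log odds ratio while the other methods estimate a
cluster-specific one, the attenuation approximation
$\hat\beta_1^* = \hat\beta_1 / (1 - \rho)$
(`marginal_to_conditional()`) converts it for cross-method bias
comparisons. Inside the harness $\rho$ is the scenario's known design
ICC; for real data `conversion_icc = "estimated"` substitutes the
fitted working correlation.

**Fixed cluster effects** (`"fixed_effects"`).
Ordinary logistic regression with indicators for clusters
$2, \dots, M$, fitted by IRLS (`stats::glm.fit`); the intervention
effect is tested by a 1-df chi-squared Wald statistic. A diverging
*treatment* coefficient ($|\hat\beta_1| > 15$) is declared separation
and reported as non-convergence. A cluster with no events at all only
sends its own nuisance indicator towards $-\infty$; its IRLS weights
vanish and the treatment inference is unaffected, so such fits are
kept. (With three clusters, losing a third of the data usually drags
the treatment coefficient along, which the rule then catches — this
reproduces the qualitative failure pattern of the study: frequent
fixed-effects failures with 3 small clusters, none with 18 or more.)

**Cluster summaries** (`"cluster_summaries"`).
The cell proportions $\pi_{jk} = \sum_i Y_{ijk} / n_{jk}$ are modelled
by the linear mixed model
$\pi_{jk} = \beta_0 + a_{0k} + \beta_1 X_{jk} + \beta_2 j + e_{jk}$,
fitted by REML. Cells enter unweighted, one row each, as the model is
defined. The variance ratio $\lambda = \sigma_u^2 / \sigma_e^2$ is
profiled out (closed-form GLS at fixed $\lambda$; Brent search over
$\log\lambda \in [-15, 15]$, with the lower boundary treated as
$\hat\sigma_u = 0$). $\hat\beta_1$ is a **risk difference**; its Wald
statistic uses the containment $t$ reference with $N$ counting cells.
The harness compares it against the true risk difference implied at
the baseline mean (0.1 for the three-step study's doubling from 0.1
to 0.2; 0.05 for the six-step study), and reports per cent bias by the
same $100(\hat\beta_1 - \beta_1)/\beta_1$ formula as the log-odds
methods.

### Time adjustment

`time_adjustment` is `"linear"` (period index as one covariate — how
the study's primary analyses adjust, matching the linear-in-logit
generation), `"categorical"` (one indicator per period $j > 0$), or
`"none"`. Omitting adjustment when a real trend exists biases every
method, because the staggered rollout confounds time with treatment;
adjusting when no trend exists costs substantial power. Both behaviours
are exercised in the test suite as directional properties.

## The Monte-Carlo harness

`run_scenario()` simulates `replicates` datasets, fits every requested
method to each, and summarises per method: mean estimate, per cent bias
$100(\bar{\hat\beta_1} - \beta_1)/\beta_1$, the rejection rate of
$p < 0.05$ (type I error under a null intervention effect, power
otherwise — strict inequality, as defined), its binomial Monte-Carlo
standard error $\sqrt{r(1-r)/n}$, and convergence accounting. Bias and
rejection summaries use converged fits only; failures are counted, not
imputed. `run_grid()` maps this over a factor grid —
`scenario_a_grid()` enumerates the three-step study's 240
configurations (clusters $\{3,6,9,18,36\}$ × cells $\{5,10,50,100\}$ ×
ICC $\{0.01,0.05,0.1\}$ × time OR $\{1,1.227\}$ × intervention OR
$\{1,2.25\}$ at $\mu = 0.1$), and `scenario_b_grid()` the six-step
study's 192 (clusters $\{6,12,18,36\}$ × cells $\{5,10,25,50\}$ × ICC
$\{0.01,0.05,0.1\}$ × time OR $\{1,1.03\}$ × intervention OR
$\{1,1.33\}$ at $\mu = 0.2$). The six-step design is given
$6 + 1 = 7$ measurement periods, mirroring the steps-plus-baseline
structure of the three-step design.

### Reproducibility

Randomness is organised so that results are bit-reproducible and
independent of execution order: each replicate owns an L'Ecuyer-CMRG
stream spawned deterministically from the scenario's master seed
(`sw_streams()`), and a discarded dataset advances to the next
*sub*stream of its own stream, so replicate $r$ is unaffected by
discards elsewhere. Within a grid, scenario $i$ derives its seed
deterministically from the master seed and its grid position, so
scenarios are independent work units that may be executed in any order
(or distributed over workers) without changing a single bit of the
result.

## Replicate counts and problem sizes

The original study used 2000 replicates per scenario (binomial standard
errors of about 0.009 for power and 0.005 for type I error). The
package defaults to 2000 as well; the test suite and the acceptance
script use 200–500 replicates per scenario, which we consider the
sensible scale for routine verification, with all stochastic
comparisons made at three binomial Monte-Carlo standard errors of the
reduced count. Tests on analytic identities (quadrature versus dense
integration, sandwich algebra, closed-form collapses) are at
$10^{-6}$–$10^{-8}$ tolerances and do not depend on replicate counts.

## Reproduction notes and known limitations

* **GEE variance flavour.** The reference results this package
  reproduces describe robust-variance GEE inference, yet their printed
  GEE power values agree with the model-based (working covariance)
  standard error and not with the sandwich, which is higher-powered and
  anti-conservative at 3 clusters (our sandwich matches an independent
  GEE implementation to about $10^{-7}$ in the test suite, so the
  difference is not an implementation artefact). `sw_fit` results
  therefore carry both standard errors; the table-reproduction test
  uses `se_type = "model"`, while the default remains the robust
  sandwich as described. Either way, GEE inference with very few
  clusters is unreliable.
* **Convergence-failure counts** are optimiser-specific and are not
  reproduced numerically; only their qualitative pattern (failures
  concentrated at 3 clusters with small cells; none at 18+ clusters
  with cells of 50+) is asserted.
* **Containment degrees of freedom** are computed from the rank of the
  combined fixed-plus-cluster design. For subject-level models these
  df are large and the $t$ reference is close to normal; the
  correction matters mainly for the cell-level cluster-summaries
  model.
* The cluster-summaries power at ICC 0.1 with 3 clusters runs a few
  points above the published value in our replications; all
  neighbouring cells and every other method agree within Monte-Carlo
  tolerance, and we have not identified a further specification detail
  that would close the gap.

## A worked example

```{r example, eval = FALSE}
sc <- sw_scenario(steps = 3, n_clusters = 6, cell_size = 50,
                  baseline_mean = 0.1, icc = 0.05,
                  or_intervention = 2.25, or_time = 1.227,
                  replicates = 200, seed = 42)
trial <- sw_simulate(sc, stream = sw_streams(42, 1)[[1]])
sw_fit(trial, "glmm")
res <- run_scenario(sc, methods = c("glmm", "gee"))
res[, c("method", "percent_bias", "rejection_rate", "mc_se_rejection")]
```
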