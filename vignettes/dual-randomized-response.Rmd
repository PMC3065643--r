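---
title: "Estimating prevalence and cheating from dual RR/DQ surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prevalence and cheating from dual RR/DQ surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualRR)
```

## The problem

Randomized response (RR) protects respondents answering sensitive
questions: a randomizing device (for example two dice) sometimes forces a
"yes" or a "no", and otherwise lets the respondent answer truthfully.
Because the interviewer never sees the device's outcome, no individual
answer is incriminating, yet the population prevalence of the sensitive
behaviour remains estimable once the misclassification induced by the
device is modelled. Some respondents nevertheless ignore the device and
always give the least stigmatizing answer — self-protective "no" (SP-no)
saying, which we call *cheating*. Unmodelled cheating biases prevalence
estimates downward.

A single sample cannot separate cheating from low prevalence: with `J`
binary questions there are `2^J - 1` independent frequencies but
`2^J - 1` latent-prevalence parameters plus a cheating rate. A *dual
sampling scheme* — the same questions asked under RR in one sample and by
direct questioning (DQ) in another — supplies `2(2^J - 1)` frequencies
and identifies both the prevalence and *design-specific* cheating rates
(`identifiability_count(3)` gives 14 frequencies against 9 parameters).
The package implements this dual mixture model, with maximum-likelihood
and Bayesian (data-augmentation MCMC) inference, the classical
single-sample RR and Clark–Desharnais two-sample models as special cases,
and a survey simulator.

## The model

For respondent $i$ in sample $s \in \{1, 2\}$ with observed answer
profile $k \in \{1, \dots, K\}$ ($K = 2^J$, profile $K$ = all-no):

$$\pi^*_{is} \;=\; (1 - \tau_{is})\, P_s\, \pi \;+\; \tau_{is}\, v,$$

where $P_s$ is the column-stochastic misclassification matrix of the
design used in sample $s$ (a Kronecker product of per-question matrices
for profiles; the identity for DQ), $\pi$ is the latent profile
prevalence, $v$ is the $K$-th unit vector (the degenerate cheating
component), and the cheating probability follows a logistic regression
$\tau_{is} = \operatorname{logit}^{-1}(x_{is}^\top \beta_s)$. The latent
distribution is parameterized log-linearly, $\log \pi = \lambda_0 + Z
\lambda$ with effect coding ($+1$ yes, $-1$ no) and $\lambda_0$ derived
so that $\pi$ sums to one; optimization and sampling are therefore
unconstrained in $(\lambda, \beta_1, \beta_2)$. Effect coding gives the
three-way term its clean interpretation: the ratio of conditional odds
ratios of two questions across the third equals $\exp(8\lambda_7)$.

The Clark–Desharnais model — two forced-yes designs, one shared cheating
proportion $\gamma$, honest-yes $\alpha$ and honest-no $\beta$ with
$\alpha + \beta + \gamma = 1$ — maps onto this family via $\tau = \gamma$
and $\pi_{\text{yes}} = \alpha / (\alpha + \beta)$
(`cd_to_spno()` / `spno_to_cd()`); reporting $\pi$ as a population
prevalence assumes cheaters are a random sample of the population.

## Parameters that matter

* **Device probabilities** (`rr_device`): per-question probabilities of a
  truthful answer, a forced yes and a forced no; they must sum to one.
  The default used throughout, `two_dice_device()`, is the classical
  two-dice design (truthful 27/36, forced yes 6/36 for dice sums 2–4,
  forced no 3/36 for sums 11–12). The motivating survey used an
  *adapted* forced-response design whose exact probabilities are not
  public, so the device is an explicit, overridable argument everywhere
  and a limitation discussed below.
* **Prior bounds** (`prior_spec`): uniform $(-b, b)$ priors on each
  $\lambda$ and $\beta$, default $b = 10$ — wide enough to contain any
  realistic log-linear term or log odds ratio without favouring values.
  `prior_sensitivity()` refits under several widths; a posterior mean
  that tracks the width while the median stays put marks a weakly
  identified parameter.
* **Chain lengths**: mixture models mix slowly; defaults are 50,000
  burn-in plus 50,000 retained sweeps. The package's own validation runs
  use 20,000 + 20,000 (survey-size problems), which keeps Monte-Carlo
  error in posterior means near the third decimal.

## Inference

**Maximum likelihood** (`fit_ml`) maximizes the unconstrained
log-likelihood by multi-start BFGS (default 10 jittered starts) with the
analytic score: the $\lambda$-gradient uses
$\partial \log \pi_k / \partial \lambda = Z_k - \sum_m \pi_m Z_m$ and the
$\beta$-gradient the usual logistic form. BIC uses the total respondent
count over both samples. Because the two cheating intercepts absorb the
all-no cells, the covariate-free model fits cell $K$ of both samples
exactly — a useful internal check. Standard errors come from the
observed information (finite differences of the analytic score);
`wald_screen()` reports univariate $z$ statistics at a 10% screening
level and never auto-selects a model. Cheating intercepts escaping to
$\pm\infty$ (boundary solutions, common in RR data) are reported with a
boundary flag.

**Bayesian inference** (`fit_bayes`) is a bespoke Metropolis-within-Gibbs
sampler with the cheating indicators $c_{is}$ as augmented data — the
augmentation odds $\tau_{is} v_k : (1 - \tau_{is})(P_s \pi)_k$ are the
model's central computation, so they are implemented literally rather
than delegated to a probabilistic-programming runtime. Only respondents
observed in category $K$ can have $c_{is} = 1$, which also means the
mixture has no label-switching problem: the cheating component is
structurally pinned to the all-no cell. Each sweep draws the indicators
(aggregated to one binomial per sample when there are no covariates),
then updates $\lambda$ componentwise given the non-cheaters' latent
multinomial, then each $\beta_s$ componentwise given the indicators'
logistic likelihood. Uniform priors are enforced by hard rejection.
Proposal scales adapt during burn-in towards a 20–45% acceptance rate
and are frozen afterwards.

Componentwise walks alone mix badly here: latent cells that the data
leave nearly empty open long flat ridges in $\lambda$ space. Each sweep
therefore also makes one joint $\lambda$ proposal with covariance
estimated from the burn-in history (scaled from $2.38/\sqrt{q}$, the
usual multivariate random-walk scaling). This markedly improves Geweke
diagnostics on sparse simulated data. Convergence checking follows the
single-long-chain practice: `geweke_diagnostic()` compares the first 10%
against the last 50% of a chain with AR-spectral variance estimates.

**Goodness of fit** (`posterior_predictive_check`) uses the realized
Pearson discrepancy over all $2K$ cells (both samples pooled): per
retained draw, $T_{\mathrm{obs}}$ compares observed counts with expected
counts under that draw, a replicate table is drawn multinomially from the
same draw and scored as $T_{\mathrm{rep}}$, and the p-value is
$\Pr(T_{\mathrm{rep}} \ge T_{\mathrm{obs}})$. The check is restricted to
covariate-free fits, where the model lives on the frequency scale; for
covariate models the function refuses with an explanation. Default 4,000
evenly spaced draws.

## The simulator

`simulate_survey()` is the generative twin of `cell_probabilities()`:
covariates are drawn from marginal generators (attitude scores from the
packaged survey marginals, Sex Bernoulli(0.5), Age uniform on −20..20),
the cheating indicator is Bernoulli with the logistic probability, a true
profile is drawn from $\pi$ (also for cheaters, so both reporting
conventions can be tested), and the observed category is either the
all-no profile or a draw from the design column of the true profile.
Draw order is fixed and driven by one seed, so runs are bit-for-bit
reproducible. What it does **not** emulate: covariates are independent
of each other and of the latent profile (only marginals are available
for the survey), $\pi$ does not depend on covariates, and there is no
item non-response. Passing recovery tests therefore validates the
estimators under the model's own assumptions, not against the full
messiness of field data.

`recovery_study()` runs simulate–fit replicates and reports bias, RMSE,
Monte-Carlo standard errors and (for MCMC) credible-interval coverage.
A `transform` argument reports recovery on a derived scale — by default
raw $(\lambda, \beta)$, but the probability scale $(\pi, \beta)$ is the
recommended reporting scale because individual $\lambda$s are
boundary-prone whenever a latent cell is nearly empty.

## Numerical choices and degenerate inputs

* `pi_from_lambda` subtracts the maximum of $Z\lambda$ before
  exponentiation; `lambda_from_pi` refuses zero cells and suggests an
  epsilon perturbation.
* A predicted probability of exactly zero for an observed cell yields a
  $-\infty$ log-likelihood with a warning (not a clamp), so optimizers
  are repelled from measure-zero configurations.
* Design matrices are validated as column-stochastic to $10^{-12}$ and
  rejected when the condition number exceeds $10^{12}$ (the design must
  be invertible for moment-type estimation). `sp_no_matrix()` output is
  exempt from the invertibility check since $\tau = 1$ is legitimately
  singular.
* Expected counts below $10^{-8}$ in the Pearson denominator are guarded
  with a warning.
* Ties in `compare_bic()` preserve input order; fits are compared only
  when their data fingerprints agree.

## Validation scale and known limitations

The package's checks run at deliberately chosen problem sizes: MCMC
validation on the survey data uses 20,000 + 20,000 sweeps; simulator
convergence checks use $n = 100{,}000$; ML recovery uses 20 replicates
of $n = 5{,}000 + 5{,}000$; MCMC coverage uses 20 replicates of the
survey sizes (1,760 + 467) at 10,000 + 10,000 sweeps.

Two limitations deserve emphasis.

1. **The device of the motivating survey is not public.** Under the
   two-dice default the covariate-free ML deviance on the packaged
   tables is 5869.1 and the posterior mean of the RR cheating rate is
   about 0.10–0.11, whereas the published analysis (under the survey's
   unpublished adapted device) reports 5872.2 and 0.157; the DQ cheating
   rate and the prevalence vector agree to well within posterior
   uncertainty. Inverting the device from the published estimates points
   to roughly (forced yes 0.19, forced no 0.02), which matches no
   documented design, so the package keeps the two-dice default and
   treats the device as required, logged configuration. The posterior
   predictive p-value moves for the same reason (about 0.2 versus the
   published 0.085: a better-fitting design leaves less realized
   discrepancy).
2. **Credible-interval coverage at survey size is below nominal.** With
   latent cells whose expected counts are below one, the bounded
   uniform priors dominate the flat likelihood directions and
   frequentist coverage of the 95% intervals falls below nominal (the
   coverage study in the test suite observes roughly 0.8 across the
   reported probabilities and coefficients at the survey sample sizes
   and 10,000 + 10,000 sweeps). This is the same mechanism behind the
   published prior-sensitivity finding for the Sex coefficient:
   weakly identified directions make posterior means, and to a lesser
   degree intervals, prior-dependent.

## Open design choices made here

* The DQ sample is represented as an RR design with an identity matrix,
  so one code path serves both samples.
* Categories are 1-based and ordered lexicographically with yes before
  no; the all-no profile is always category $K$. This is enforced at
  construction and not configurable, because the SP-no component targets
  category $K$ by definition.
* Per-cell versus per-respondent augmentation are both implemented (the
  sampler aggregates automatically when no covariates are present); they
  are equivalent by sufficiency.
* Thinning is off by default; storing every post-burn-in draw is cheap
  at this scale.
* The Wald screen is advisory; model choice is left to the analyst, with
  `compare_bic()` for support.
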