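---
title: "Methods: combining inverse-probability weighting and multiple imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining inverse-probability weighting and multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipwmi)
```

## The problem and the estimator

Cohort and survey analyses routinely face two qualitatively different
kinds of missingness at once: whole blocks of variables missing on some
individuals (a missed follow-up visit, an unanswered questionnaire
module, deliberate subsampling) and scattered single missing values on
the rest. Full multiple imputation (MI) must then model the joint
distribution of the whole block — a multivariate model that is easy to
get wrong; inverse-probability weighting (IPW) needs only a univariate
model for the probability of being included, but discards the partially
observed individuals and is inefficient.

IPW/MI splits the difference. An **inclusion rule** $g(R)$, a
deterministic function of the missingness pattern $R$ only, decides who
enters the analysis (here: individuals with the designated variable block
fully observed, `rule_block_complete()`). A **missingness model**
$\pi(Z;\alpha)$ for $P(g(R)=1 \mid Z)$ is fitted by maximum likelihood to
*all* $N$ individuals, where $Z$ is fully observed; included individuals
receive weight $W = 1/\hat\pi$. Remaining missing values among included
individuals are **properly imputed** $M$ times; each quasi-complete
dataset is analysed by weighted estimating equations

$$\sum_{i \in I} W_i\, \tilde x_i \{Y_i - \mu(\tilde x_i'\theta)\} = 0,$$

with the robust sandwich variance $\hat U = A^{-1} B A^{-1}$,
$A = \sum W_i v_i \tilde x_i \tilde x_i'$,
$B = \sum W_i^2 \hat e_i^2 \tilde x_i \tilde x_i'$ (identity link:
`wls_fit()`; logit link: `weighted_logistic_fit()`, damped Newton with
step-halving, convergence when the largest score component is below
$10^{-9}$). The $M$ fits are pooled by Rubin's rules
(`pool()`): $\bar\theta_M$ is the mean of the per-imputation estimates
and $\hat\Sigma_M = \bar W + (1 + 1/M)B$ with $\bar W$ the mean
within-imputation variance and $B$ the between-imputation sample
covariance (divisor $M-1$). Per-coefficient degrees of freedom use the
classical large-sample formula
$(M-1)\{1 + \bar W_{jj}/((1+1/M)B_{jj})\}^2$; they are reported for
completeness but nothing downstream depends on them. Strategies with no
imputation return a single fit with $B = 0$ and $M = 1$ for interface
uniformity.

### Validity conditions, and when the imputer must see the weights

Consistency of the pooled estimate requires, beyond correct missingness
and imputation models, that inclusion be independent of the modelled
variables given $Z$, and — less obviously — that the missing variables be
conditionally independent of the weight given the observed variables
among included individuals. The included set over-represents
high-inclusion-probability individuals; if the conditional distribution
being imputed varies with $W$, a model fitted only to included
individuals tilts toward the low-weight stratum. The cure is to include
$W$ (or $\hat W$, or all of $Z$) among the imputation predictors. For a
*weighted linear* analysis with an imputed outcome there is a second,
variance-level requirement: the imputer must include the products of $W$
with every analysis covariate (and $W$ itself when there is an
intercept), otherwise the imputer assumes more than the weighted analyst
(equal outcome models across weight strata) and the pooled variance is
overestimated. `attach_weight_terms()` performs exactly this
augmentation and is idempotent; `validate_conditions()` checks a
strategy's specs against both requirements and warns — it never fails, as
a deliberately unaugmented imputer can be a reasonable
efficiency choice when the extra coefficients are truly zero.

Imputation models are always fitted by **unweighted** maximum likelihood
on the included individuals: weights enter imputation only as
covariates, never as fitting weights.

### Proper imputation draws

`impute_regression()` implements Bayesian normal linear-regression
imputation under the improper prior $p(\beta, \sigma_\varepsilon)
\propto \sigma_\varepsilon^{-2}$: with $n$ fitting rows and $p$
predictors, $\sigma^{2*} = \mathrm{RSS}/\chi^2_{n-p}$, $\beta^* \sim
N(\hat\beta, \sigma^{2*}(X'X)^{-1})$, and each missing outcome is drawn
as $\tilde x'\beta^* + \sigma^*\varepsilon$. `impute_mvn_block()` imputes
an all-or-nothing missing block $(d \ge 2$ jointly normal variables$)$
from the conjugate posterior under the standard noninformative
(Jeffreys-limit) normal–inverse-Wishart prior
$p(\mu, \Sigma) \propto |\Sigma|^{-(d+1)/2}$:
$\Sigma \mid \text{data} \sim \mathrm{InvWishart}(n-1, S)$ with $S$ the
centred scatter matrix, and $\mu \mid \Sigma \sim N(\bar x, \Sigma/n)$.
Any standard noninformative degrees-of-freedom convention differs only by
a bounded constant and is asymptotically equivalent; third-decimal shifts
in finite-sample average SEs are possible and accepted. Follow-on
conditional regressions (e.g. a variable whose conditional mean is a
product of two block variables) are drawn by the regression mechanics
using the drawn block values. Non-positive-definite posterior draws are
re-drawn up to 10 times and then raise an error: failing loudly beats
silent bias. Observed cells are never modified, and identical seeds give
bit-identical stacks.

### Accounting for estimated weights

Treating $\hat W$ as known is conservative for some parameters.
`adjusted_sandwich()` stacks the missingness-model score equations for
$\alpha$ above the weighted analysis equations for $\theta$ and reports
the $\theta$-block of the joint sandwich (block-Jacobian bread, stacked
per-individual score outer products as meat), with analytic Jacobians for
both the logistic and the saturated-stratum weight model. On stratified
fixtures the adjusted intercept variance is never larger than the
unadjusted one, matching the asymptotic theory; the operation refuses
known (non-estimated) weights, where the adjustment is undefined.

## The strategy engine

`strategy_spec()` names a choice per missingness stage — stage 1 the
covariate block, stage 2 the outcome — among CC (exclude, no weights),
IPW (exclude and weight) and MI (impute). Supported pairs are CC/CC,
CC/IPW, CC/MI, IPW/CC, IPW/IPW, IPW/MI and MI/MI; MI/CC and MI/IPW are
rejected, since imputing a whole block only to discard those individuals
at stage 2 combines the cost of the joint model with the efficiency loss
of exclusion. Stage ordering is fixed: stage-1 exclusion or imputation
happens first, and stage-2 weight models are fitted only among
individuals retained at stage 1 (their predictors may involve stage-1
variables, e.g. a product $X_2 X_4$). Two-stage IPW composes weights
multiplicatively: $W = 1/(\hat\pi_1 \hat\pi_2)$ (`product_weights()`).
Positivity is enforced, not assumed: fitted inclusion probabilities below
a floor ($10^{-6}$ by default) raise an error rather than being silently
truncated, because truncation changes the estimand; an explicit
`truncate = TRUE` opt-in exists.

For MI at stage 1 followed by MI at stage 2, each of the $M$ block
imputations is completed by one conditional outcome imputation, keeping
the draws properly nested. The outcome-imputer fit uses outcome-observed
rows (which, under the block-then-outcome missingness monotonicity, are
fully observed), so the between-imputation variability correctly reflects
both parameter draws.

## The synthetic-data generator and its calibration

`twostage_config()`/`generate_twostage()` implement a two-stage
missing-at-random mechanism designed to stress every failure mode the
strategies differ on: $X_1 \sim \mathrm{Bernoulli}(0.5)$;
$X_2, X_3, X_4 \sim N(0,1)$ iid; $X_5 \sim N(X_2 X_3, 1)$;

$$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_3 + \beta_4 X_4 +
\beta_5 X_5 + \beta_{12} X_1X_2 + \beta_{13} X_1X_3 + \beta_{23} X_2X_3 +
\beta_{123} X_1X_2X_3 + \varepsilon,$$

$\varepsilon \sim N(0,1)$. The block $(X_2,\dots,X_5)$ is observed with
probability $0.8 - 0.6X_1$; given an observed block, $Y$ is observed with
probability $\mathrm{expit}(1.5 - 0.6\,X_2X_4)$, and $Y$ is always
missing when the block is. The default coefficients are
$(\beta_0,\dots,\beta_{123}) = (-3, 0, 0, 0, 1, 0.5, 1, 1, 0.5, 0)$,
chosen once to satisfy, simultaneously:

* the analysis model $Y \sim X_2 + X_3 + X_2{:}X_3$ is *correctly
  specified* marginally, with truth $(\theta_0, \theta_2, \theta_3,
  \theta_{23}) = (-3, 0.5, 0.5, 1)$ — verified in closed form by
  `check_calibration()` ($\theta_0 = \beta_0 + \beta_1/2$, $\theta_2 =
  \beta_2 + \beta_{12}/2$, $\theta_3 = \beta_3 + \beta_{13}/2$,
  $\theta_{23} = \beta_{23} + \beta_{123}/2 + \beta_5$, using
  $E[X_1] = 1/2$, $E[X_4] = 0$, $E[X_5 \mid X_2, X_3] = X_2X_3$) and
  confirmed by OLS on a large fully observed draw;
* the $X_1$ interactions make the block-complete subsample conditionally
  different ($P(X_1 = 1 \mid \text{complete block}) = 0.2$, conditional
  slopes $0.2$), so unweighted stage-1 exclusion is biased;
* $X_4$ ties the outcome to the stage-2 missingness while staying out of
  the analysis model, so unadjusted stage-2 exclusion biases $\theta_2$;
* exactly half of the $X_2X_3$ signal flows through $X_5$
  ($\beta_{23} = \beta_5 = 0.5$), so a joint-normal block imputer that
  destroys the $X_5$–$X_2X_3$ mean structure shrinks the estimated
  interaction toward $0.75$, and an outcome imputer lacking the
  interaction terms shrinks it toward $0.4$ (roughly the fraction of
  observed outcomes).

These constants are the package's fixed study conditions, not tuning
knobs; everything is overridable through `twostage_config()` for other
designs. About 50% of individuals lose the block and about 60% of
outcomes are missing overall (including the block-missing individuals).

What the generator deliberately does *not* emulate: categorical or
skewed variables, nonmonotone within-block missingness,
longitudinal/repeated measures, clustering, and missingness depending on
unobserved values (not-at-random). Tests passing on this generator
therefore show correctness of the estimating machinery under a favourable
MAR design, not robustness of MI to real-data pathologies.

## The replicate harness

`run_study()` draws `nrep` datasets and applies every strategy to each,
reporting per strategy and parameter the mean estimate, the square root
of the mean estimated variance (aSE), the standard deviation of the
estimates (eSE) and the Monte-Carlo SE of the mean, `eSE/sqrt(nrep)`.
aSE/eSE $\approx 1$ is the empirical signature of a valid variance
estimator. Reproducibility: per-replicate RNG substreams derive from the
master seed, and per-strategy substreams from a stable hash of the
strategy label, so results are invariant to which other strategies run. A
replicate failing for one strategy is excluded from that strategy's
summary with a logged count, never silently.

Problem sizes used by the shipped checks were chosen to make Monte-Carlo
noise small relative to the effects being measured while keeping runs
desk-scale: the test suite runs the ten-strategy comparison at
`nrep = 250`, `N = 1000`, `M = 10` (three combined Monte-Carlo SEs on a
mean are then about $0.02$); the acceptance script runs the six
headline strategies at `nrep = 1000`; rate and distributional checks use
single draws at $N = 10^5$.

## Numerical choices

* Linear solves go through QR on the $\sqrt W$-scaled design; rank
  deficiency is decided at relative tolerance $10^{-8}$ and reported with
  the names of the dependent columns.
* The sandwich is plain HC0 form, matching the estimating-equation
  derivation; small-sample corrections (HC1/HC3) are deliberately not
  applied by default.
* Logistic fitting: at most 100 Newton iterations with up to 30
  step-halvings; separation is detected by non-convergence or fitted
  linear predictors beyond ±30 and raised as an error.
* Missing values are represented as `NA` (an explicit mask), never as a
  sentinel number; weight-model predictors must be fully observed
  wherever the model is fitted, and violations are errors, not warnings.
* Ties/degenerate cases: empty row sets build 0-row designs without
  error; a fully observed imputation target returns $M$ identical copies;
  duplicate model terms are rejected at specification time.

## Known limitations

* Only continuous (or 0/1-coded binary) variables; categorical expansion
  is the caller's responsibility, and there is no categorical imputation
  model.
* No chained-equations engine: block imputation requires the
  all-or-nothing (monotone block) structure and joint normality.
* No doubly robust augmented-IPW estimator, and no design-based
  replication variance for externally supplied survey weights.
* Two missingness stages only.
* The weight-estimation-adjusted sandwich covers the logistic and
  saturated-stratum missingness models fitted in-package; externally
  estimated weights cannot be adjusted for (their scores are unknown).
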