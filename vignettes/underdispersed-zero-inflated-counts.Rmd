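---
title: "Modelling underdispersed, zero-heavy fatality counts with the CMP family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling underdispersed, zero-heavy fatality counts with the CMP family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zicmpreg)
```

## The modelling problem

Deaths per road traffic accident are a count outcome with two unusual
features at once.  First, the outcome is *underdispersed*: the sample
variance is smaller than the mean, the opposite of the overdispersion that
negative-binomial models address.  Second, the zero count is very heavy —
in the packaged 2015 Thailand data roughly 72% of crashes killed nobody —
which raises the question of whether a separate "structural zero" process
(accidents that could never have been fatal) sits on top of the ordinary
count process.

`zicmpreg` fits four nested models to such data by maximum likelihood:

* **Poisson**: $\lambda_i = \exp(X_i'\beta)$, equidispersed by construction.
* **CMP** (Conway–Maxwell–Poisson): pmf
  $\Pr(Y=y) = \lambda^y / \{(y!)^\nu Z(\lambda,\nu)\}$ with
  $Z(\lambda,\nu)=\sum_{j\ge0}\lambda^j/(j!)^\nu$ and a dispersion link
  $\nu_i = \exp(S_i'\delta)$.  $\nu>1$ yields underdispersion, $\nu=1$
  recovers Poisson, $\nu<1$ overdispersion; approximately
  $\mathrm{Var}(Y)/E(Y)\approx 1/\nu$.
* **ZIP**: a point mass at zero with probability
  $\pi_i = \mathrm{logit}^{-1}(W_i'\gamma)$ mixed with Poisson.
* **ZICMP**: the same zero mixture over a CMP count part, i.e. all three
  linear predictors at once.

The models nest (Poisson $\subset$ CMP, ZIP $\subset$ ZICMP via $\delta=0$;
Poisson $\subset$ ZIP, CMP $\subset$ ZICMP via $\pi\to0$), which supports
likelihood-ratio tests for dispersion ($H_0{:}\ \nu=1$) and for zero
inflation ($H_0{:}\ \pi=0$), each referred to $\chi^2_1$.  A score test
for zero inflation needs only the Poisson fit:
$S = (n_0 - n p_0)^2 / \{n p_0(1-p_0) - n\bar y p_0^2\}$ with
$p_0 = e^{-\bar y}$.

## Numerical treatment of the normalizing constant

$Z(\lambda,\nu)$ is an infinite series.  The package accumulates its
logarithm term-by-term with a running log-sum-exp.  The log-terms
$j\ln\lambda - \nu\ln j!$ are unimodal in $j$ with mode near
$\lambda^{1/\nu}$, so truncation stops only once the index has passed the
mode *and* the current term is below `rel_tol` times the accumulated sum
(default $10^{-12}$, hard cap `max_terms = 10000`).  Stopping on a small
term before the mode would truncate the bulk of the mass.  Two special
cases: $\nu = 1$ gives $Z = e^\lambda$ exactly (every CMP quantity then
reduces to its Poisson counterpart, which the tests verify to $10^{-10}$),
and $\nu = 0$ is admitted only with $\lambda < 1$, where the series is
geometric; $\nu=0,\lambda\ge1$ diverges and is rejected with an explicit
error.  $\ln y!$ is always computed via `lgamma(y + 1)`, never by forming
$y!$.

Two mean/variance forms are provided by `cmp_moments()`.  The *exact*
moments sum $j\,p(j)$ and $j^2 p(j)$ over the truncated support and are the
package default, used in predictions and Pearson statistics.  The
*asymptotic approximations* $E(Y)\approx\lambda^{1/\nu}-(\nu-1)/(2\nu)$
and $\mathrm{Var}(Y)\approx\lambda^{1/\nu}/\nu$ are kept as an explicit
`method = "approx"` because reported results in this literature often use
them; at small rates they are materially biased (at
$\lambda\approx0.33,\nu\approx1.55$ the approximation gives 0.313 against
an exact mean of 0.302), so the two must never be mixed silently.
Relatedly, `pearson_gof()` has a labelled `"squared_deviation"` variant —
the frequency-weighted sum of squared deviations about the *approximate*
CMP mean, with no scaling by the mean — which reproduces a reporting
convention seen for CMP-family fits; the default `"pearson"` variant is
the standard $\sum w_i(y_i - E Y_i)^2/E Y_i$ with exact means.

## Fitting: optimizer, starts, boundaries

All fits maximize the exact weighted log-likelihood.  A frequency table
(distinct count value, number of accidents) is expanded to one weighted
row per value; this is algebraically identical to record-level fitting,
and the tests confirm equality of log-likelihoods to $10^{-8}$.

The Poisson part is an ordinary log-link GLM and is solved by
`stats::glm.fit` (IRLS to $10^{-14}$), so the intercept-only estimate is
$\ln\bar y$ to machine precision.  CMP, ZIP and ZICMP use BFGS on the
unconstrained $(\beta,\delta,\gamma)$ scale with analytic gradients: the
CMP score needs only $E[Y]$ and $E[\ln Y!]$, both computed from the same
truncated series as $Z$.  Convergence uses a relative-tolerance of
$10^{-12}$ with at most 500 iterations.  Three safeguards matter in
practice, all deterministic:

1. **Multi-start.** The zero-mass/rate trade-off makes the likelihood a
   curved ridge.  Besides the default start ($\beta$ from the Poisson
   fit, $\delta=0$, $\gamma$ at the logit of the excess-zero fraction),
   the zero-inflated kinds try moment-informed starts at $\pi_0 = 0.1$
   and $0.3$ and keep the best optimum.
2. **Restart.** One BFGS restart from the first optimum (resetting the
   curvature approximation) recovers slow progress along flat ridges.
3. **Boundary candidate.** $\pi = 0$ lies at $\gamma\to-\infty$, outside
   the logit parameterization, so the optimizer cannot reach it.  An
   explicit candidate with the zero-part intercept at $-30$ (and a
   re-optimization of the other parts from there) is always evaluated;
   if it wins, the fit is the no-inflation boundary solution.

The zero-part linear predictor is clamped at $\pm30$ inside the
likelihood.  Any zero-part coefficient with $|\hat\gamma_j|\ge10$ is
flagged `boundary`: beyond that point $\pi$ differs from 0 or 1 by less
than $5\times10^{-5}$, the likelihood is flat to numerical precision, and
Wald standard errors are meaningless.  The threshold is deliberately
below the clamp because the optimizer legitimately stops anywhere on the
flat stretch; flagging only at the clamp itself would miss real boundary
solutions.  Standard errors come from the inverse numerical Hessian of
the negative log-likelihood at the optimum (central differences of the
analytic gradient); when boundary coefficients make the full Hessian
singular, the interior block is inverted and the flagged entries are
reported as `NA`.

Degenerate inputs are rejected with explicit errors: an all-zero outcome
(no identifiable rate), rank-deficient design matrices, unknown factor
levels (reported with the record index), negative weights.

## What the synthetic-data generator does and does not emulate

`simulate_covariates()` draws the six categorical covariates (roadway
class, road surface, road section, weather, light condition, month)
independently from marginals that default to the observed 2015 Thailand
proportions (`thai_marginals()`), and `simulate_fatalities()` draws
deaths per record from a ZICMP regression at user-specified coefficients
via exact cdf-inversion sampling.  Two real-data features are *not*
emulated: dependence between covariates (the real pairwise associations
are weak, Cramér's V $\le 0.59$, but not zero) and any spatial or
temporal correlation between accidents.  Passing recovery tests on this
generator therefore demonstrate that the estimation machinery is
correctly calibrated for independent records under the assumed model —
they do not validate the model against real accident processes.

## Weak identification near the zero-inflation boundary

A point that shapes both the package defaults and what simulation can
show: when the count-part rate is small, a ZICMP with moderate $\pi$ is
nearly indistinguishable from a plain CMP with slightly different
$(\lambda,\nu)$.  At $(\lambda,\nu,\pi) = (0.33, 1.55, 0.27)$ the
Kullback–Leibler divergence from the nearest zero-free CMP is about
$3\times10^{-5}$ — an expected log-likelihood-ratio of only $0.33$ at
$n=5{,}000$.  In that regime a large fraction of replicates have their
global maximum exactly at the $\pi=0$ boundary, no Wald interval for
$\gamma$ exists, and confidence-interval calibration experiments are not
meaningful.  `recovery_experiment()` therefore reports boundary
collapses separately (`n_boundary` attribute) and computes coverage over
the replicates with valid intervals, and the packaged calibration check
runs at truths with a clearly identifiable zero part
($\beta_0=0.5,\ \delta_0=0.4,\ \gamma_0=-1$; KL $\approx5\times10^{-3}$),
where 95% Wald coverage lands at 0.96–0.98 over 50 replicates of
$n=5{,}000$.  This is the same phenomenon seen in the real fatality
table, where the fitted zero part collapses to the boundary and the
zero-inflated models add nothing over their restricted counterparts.

The $\chi^2_1$ reference is used as-is for the zero-inflation LRT even
though the null value $\pi=0$ sits on the parameter boundary; this
matches the convention of the applied literature this package follows and
is conservative (the boundary-corrected null would be a 50:50 mixture of
$\chi^2_0$ and $\chi^2_1$).  The tests verify empirically that the
resulting rejection rate under a no-inflation null stays at or below
nominal.

## Worked analysis of the packaged frequency table

```{r table, eval = FALSE}
ft <- thai_fatalities_2015()
report <- run_pipeline(ft)
report
```

This fits all four intercept-only models, prints the comparison block
(log-likelihood, AIC, Pearson statistics, parameter counts, boundary
flags) and the dispersion LRT, zero-inflation LRTs and score test.  On
the packaged table the CMP dispersion estimate is
$\hat\nu = e^{0.4384} \approx 1.55$ (underdispersion), the dispersion LRT
is 85.87 ($p<10^{-4}$), the score test is 177.69 — yet both zero-inflated
fits collapse to the boundary, illustrating that a significant score
test need not imply a recoverable zero-inflation component once
dispersion is modelled.

## Problem sizes used in the test suite

The suite fits intercept-only models on 7-row weighted tables (fast),
one record-level design of $n=20{,}229$ with a 12-level month zero part,
a 50-replicate recovery experiment at $n=5{,}000$, a 200-replicate
zero-inflation LRT size check at $n=2{,}000$ per replicate, and a
1,000-replicate score-test size check at $n=2{,}000$.  These sizes give
Monte-Carlo standard errors small enough for the stated tolerance bands
(binomial SE $\approx0.007$ on a 5% rejection rate at 1,000 replicates)
while keeping the default test run in the low minutes.

## Known limitations

* Dispersion and zero parts are linear on their link scales; no smooth
  terms or random effects.
* No exposure offsets (accident duration, traffic volume).
* The asymptotic moment approximations are provided for reproduction and
  comparison only; they should not be used for prediction at small rates.
* Negative-binomial and geometric alternatives are out of scope.
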