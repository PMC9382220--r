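---
title: "Models and methods behind bibquality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bibquality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bibquality` asks a measurement question: do citation counts and journal
impact factors (JIFs) track observable indicators of research quality?
The package operationalizes three such indicators for literatures that
report statistics in APA style — the accuracy of statistical reporting,
the evidential value of reported tests, and replication success — and
provides the full chain from raw text to hierarchical Bayesian models,
together with a synthetic-corpus generator so that every stage can be
validated against known ground truth. This vignette documents the
models, the numerical choices, and the design decisions that were
genuinely open.

## 1. Reporting accuracy: recomputation and decision errors

Each extracted report (`t(df) = x, p = v` and its F, r, chi-squared and
z analogues) carries enough information to recompute the p-value from
the statistic and degrees of freedom: central t, F and chi-squared
distributions, the exact `t = r * sqrt(df/(1-r^2))` transform for
correlations, and the standard normal for z. t, r and z are treated as
two-tailed unless the text flags a one-tailed test; F and chi-squared
are inherently one-tailed.

A report is *consistent* when the reported comparator is compatible
with the recomputed p under a rounding-aware policy: `p = v` printed at
`d` decimals is compatible whenever the recomputed value lies within
half a unit in the last printed digit of `v`; `p < v` requires the
recomputed p to be below `v`; `p > v` above; `ns` above alpha. An
incompatible report whose significance status at alpha = 0.05 agrees
with the recomputed status is an *inconsistency*; disagreement is a
*decision error*, an overclaim when significance was reported but not
supported, an underclaim in reverse. Two boundary rules are fixed
because published sources rarely state them: a reported `p = .05`
counts as a claim of significance (`p <= .05`), and a reported `p =
.05` whose recomputed value lies in (0.05, 0.055) is treated as
rounding, not as a decision error. Both choices are conservative and
applied uniformly.

Articles with fewer than two tests are excluded (they are mostly
commentaries and permit no within-article variability), and analyses
can be run with chi-squared reports removed entirely, because
automated extraction sometimes miscodes a chi-squared sample size as
its degrees of freedom; records where `df > N/2` alongside a reported
N are additionally flagged as suspect. Exclusion, not repair, is the
supported response to the miscoding.

## 2. Evidential value: default JZS Bayes factors from summary statistics

For every significant t test, one-df F test and Pearson r (recomputed
p at or below 0.05), the package computes the default
Jeffreys–Zellner–Siow Bayes factor comparing a Cauchy(0, 0.707) prior
on the standardized effect size against a point null. Only the
statistic and its degrees of freedom are available, so sample size is
reconstructed as `N = df + 1` (one-sample reading) and `N1 = N2 =
(df + 2)/2` (two-sample reading), with half-integers rounded away from
zero — the rounding direction is a fixed convention, since "nearest
integer" leaves ties open. Both design readings are scored because the
text does not reveal the design; across corpora their log Bayes
factors correlate near 1 by rank, and downstream models use the
two-sample variant.

The marginal likelihood under the alternative is
`m1 = ∫ T_df(t; δ√Neff) Cauchy(δ; 0, r) dδ`, evaluated by adaptive
quadrature after the substitution `δ = r·tan(θ)`, which turns the
Cauchy weight into a uniform density on (−π/2, π/2). Everything is
computed in log space. Two numerical points deserve note:

* The noncentral t density is computed from its exact integral
  representation (an inner log-space quadrature centred at the
  integrand's Laplace point) rather than from the stock distribution
  function, whose absolute error floor of roughly 1e-8 surfaces as a
  spurious far-tail plateau wide enough to bias the Bayes factor at
  the package's 1e-6 accuracy target.
* The θ axis is truncated where the integrand falls ~e^-34 below its
  peak; the discarded mass is orders of magnitude below the quadrature
  tolerance.

The test suite checks this engine against an independent quadrature of
the same Bayes factor in its auxiliary-variance form (the
inverse-gamma mixture representation of the Cauchy prior), a route
that shares no code and no distribution functions with the
implementation.

Bayes factors are re-expressed as probabilities `BF10/(BF10+1)` —
computed from the log Bayes factor, so extreme values cannot overflow
— and records whose probability is indistinguishable from 1 in double
precision (log BF10 > 53·log 2) are flagged and dropped from
probability-scale analyses rather than clamped. The two-proportion
Bayes factor used for the overclaim/underclaim asymmetry is the exact
beta-binomial marginal-likelihood ratio under Beta(1,1) priors,
computed with log-beta functions.

## 3. The hierarchical models

Three response types map to three models, all fitted by Gibbs/slice
sampling through JAGS with explicit per-chain seeds:

* **Error counts**: a zero-inflated Poisson regression with
  `log lambda = X beta + log(n_tests) + u_area` and a constant
  zero-inflation probability on the logit scale. The log-exposure
  offset makes the Poisson component a per-test error *rate*; the
  zero-inflation component absorbs the excess of error-free articles.
  The mixture is marginalized analytically inside the sampler (the
  "zeros trick") because the latent-indicator parameterization couples
  the inflation probability to the Poisson zeros and mixes an order of
  magnitude more slowly.
* **Evidence probabilities** (and, in an exploratory variant,
  significant recomputed p-values rescaled by 1/alpha): beta
  regression with a logit-linked mean, area random intercepts, and a
  constant precision phi parameterized as `phi = s^-2` with a
  half-normal prior on `s`, which is diffuse over large precisions.
  Responses touching 0 or 1 are rejected; the standard compression
  `(y(n-1)+0.5)/n` is provided for boundary-valued responses.
* **Replication success**: multilevel logistic regression with random
  intercepts for content area *and* publication year (year is a
  grouping factor here; in the other two models it is a standardized
  fixed effect — the replication data are too small to estimate a
  smooth year trend, and the collation spans heterogeneous project
  waves).

"Weakly regularizing" priors are fixed as Normal(0, 2.5) on fixed
effects, Half-Normal(0, 1) on group-level standard deviations and the
beta dispersion scale, and Logistic(0, 1) — uniform on the probability
scale — on the zero-inflation intercept. Predictors enter as ln(JIF),
ln(citations + 1), standardized year, and the author count raw in the
error/evidence models but ln-transformed in the replication model.
Journal is never a grouping factor: it is collinear with JIF by
construction. Design columns are centred (not scaled) before sampling,
so slopes keep their per-unit interpretation while the intercept — the
value at covariate means — decorrelates from them; the random-intercept
mean is swept into the intercept per draw (a sum-to-zero
reparameterization of the identical posterior) for the same reason.

Every fit reports split-Rhat and effective sample size per
coefficient and *fails* — rather than warns — when any fixed effect
has Rhat above 1.01 or ESS below 400 under the default control.
Simulation studies that only read coverage off credible intervals run
shorter single chains with the gate relaxed; those settings are local
to the simulations and documented where used.

## 4. Predictor Bayes factors, LOO R², posterior predictive checks

Per-predictor evidence is computed by the Savage–Dickey density ratio:
prior density at zero over posterior density at zero, the latter
estimated from the draws by a Gaussian kernel with Silverman's
bandwidth, evaluated in log space, with a two-bandwidth Richardson
extrapolation that cancels the kernel's O(h²) curvature bias — material
when the null lies in the posterior's tail. The estimator is checked
against the closed-form Bayes factor of a conjugate normal toy model.
Tail density estimation from draws is noisy by nature; the check uses
a large draw count, and applications should treat single-digit
percentage accuracy as the realistic ceiling.

Out-of-sample fit is summarized by a LOO-adjusted R²: leave-one-out
predictive means computed by Pareto-smoothed importance sampling
(generalized-Pareto fit to the top 20% of importance ratios, expected
order statistics substituted, weights truncated at the raw maximum),
then `1 - var(y - yhat_loo)/var(y)`. When the Pareto shape diagnostic
exceeds 0.7 for more than a tolerated fraction of observations the
function falls back to 10-fold cross-validation with per-fold refits.
Pure-noise responses give values near zero (possibly slightly
negative, as an honest out-of-sample estimate should).

Posterior predictive checks simulate replicate datasets from the
posterior and compare observed mean, variance and (for counts) zero
fraction against their predictive distributions via two-sided tail
probabilities; for well-specified fits these are roughly uniform, and
a plain-Poisson misfit on zero-inflated data is flagged by the
zero-fraction statistic.

## 5. The synthetic corpus: what it emulates and what it does not

The generator is the package's ground-truth instrument, and its
defaults define the simulated study conditions: about 14.8 tests per
article (shifted negative binomial), log-normal JIFs with median near
2, negative-binomial citations mildly dependent on JIF and year,
shifted-Poisson author counts, years 1985–2016, fourteen content
areas. Per-test effect sizes mix a point null (proportion 0.2) with
Cauchy(0, 0.707) alternatives truncated to |δ| < 2, coherent with the
scoring prior. Because half of those alternatives are small (|δ| <
0.707) and simulated sample sizes are modest, roughly 40% of generated
tests reach significance — lower than the ~73% seen in large
behavioural-science corpora, whose share is inflated by selective
reporting that the generator deliberately does not model. Test statistics are drawn
from the implied noncentral distributions at simulated sample sizes,
rounded to two decimals, and reported honestly (exact-p style, `<
.001` below that threshold).

Decision errors are then injected at the article level from a
zero-inflated, covariate-dependent rate model (defaults: inflation
0.3, per-test base rate 2%, log-rate slope −0.21 on centred log-JIF,
−0.11 on standardized year), by rewriting the *reported* p across the
significance boundary — overclaims become `p < .05`, underclaims
`p > .05` — while leaving the statistic untouched. This matches the
operational definition of a decision error, makes every injected error
detectable and every detected error traceable (the suites assert exact
agreement), and fixes the overclaim share at 0.84. A small fraction of
chi-squared reports (5%) carries its sample size miscoded as the
degrees of freedom to exercise the suspect-record heuristic; reported
p-values for those records follow the miscoded recomputation, so they
exercise flagging, not the error counts.

The replication generator emulates a replication-project collation:
190 studies in up to 27 journals and 7 areas, base success rate 42.1%,
logistic coefficients defaulting to −0.822 (log JIF), 0.237 (log
citations), 0.179 (log authors), and optional surprisingness/prestige
ratings with a −0.663 surprisingness effect.

What passing tests on this corpus do *not* show: the generator writes
clean APA sentences (no PDF conversion noise, no table-formatted
statistics, no non-APA dialects), reports are honest apart from the
injected errors (no p-hacking, no selective reporting), effect sizes
are independent of the bibliometric covariates, and the replication
table has no publication-bias structure. Results on real corpora
inherit none of these guarantees.

## 6. Problem sizes and reproducibility

The validation suites run at desk scale, chosen to keep each suite in
the minutes range while leaving the checks well-powered: coverage
studies use 100 replicates per model family (150-article corpora for
the error model, 250-row tables for the beta model, 190-study tables
for the logistic model) with short single chains, the JZS engine is
checked on a grid up to |t| = 20 and n = 10^4, and the end-to-end
error-rate recovery uses a 1500-article corpus of roughly 2 × 10^4
tests. Every random
step — corpus generation, MCMC, simulation loops — is driven by
explicit integer seeds, and identical seeds reproduce results exactly,
including the MCMC draws (per-chain generator seeds are derived from
the control seed).

## 7. Known limitations

* The APA grammar is a fixed core dialect; real literatures contain
  variants (decimal commas, thousands separators, confidence
  intervals, table-only statistics) that are out of scope.
* Evidence scoring covers t, one-df F and r only; multi-df F,
  chi-squared and regression statistics have no default-Bayes-factor
  treatment here.
* Sample-size reconstruction from degrees of freedom is exact only
  for balanced designs without covariates; the two design readings
  bound, but do not remove, that uncertainty.
* The Savage–Dickey estimator degrades when the posterior places
  essentially no draws near the null; extreme Bayes factors should be
  read as order-of-magnitude statements.
* Zero-inflation is constant (no covariates), matching the analysis
  it reproduces; literatures with covariate-dependent inflation would
  need an extended model.
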