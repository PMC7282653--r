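---
title: "Methods: generalized inference for fraction-retention non-inferiority"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized inference for fraction-retention non-inferiority}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracret)
```

## The model

An active-control non-inferiority trial yields an estimate of the
treatment-vs-control difference, and historical placebo-controlled trials
yield an estimate of the control-vs-placebo difference. Both are modelled
as normal:

$$\hat C_{NI} - \hat T_{NI} \sim N(\mu_{NI}, \sigma_{NI}^2), \qquad
  \hat C_{H} - \hat P_{H} \sim N(\mu_{H}, \sigma_{H}^2),$$

independent of each other. Under the constancy assumption (the control
effect in the historical setting equals what it would be in the current
trial), the new treatment's effect over placebo is
$\theta_1 = \theta_2 - \mu_{NI}$ with $\theta_2 = \mu_H$, and the quantity
of regulatory interest is the retained fraction
$\delta = \theta_1/\theta_2$. The hypotheses are
$H_0\colon \delta \le \delta_0$ against $H_1\colon \delta > \delta_0$,
equivalently $H_0\colon \mu_{NI}/\mu_H \ge 1 - \delta_0$ against the
complement. No sign assumption is placed on $\mu_H$ by the ratio or GPV
tests; Rothmann's derivation presumes a beneficial control
($\mu_H > 0$), which is also the only regime in which retention is a
meaningful goal.

## The four tests

**Rothmann** and **Wang** are standard-normal tests on, respectively, the
linear contrast $\hat m - (1-\delta_0)\hat h$ and the studentized ratio
scale; as printed, the two rejection regions are algebraically identical
whenever $\hat h > 0$, and the package's property tests verify the p-value
identity to 1e-12 on random summaries. The published critical-value
notation for these tests is ambiguous about sign conventions (an "upper
critical point" paired with a "<" region), so the package works purely in
p-value space — Rothmann p is the lower normal tail of $Z_R$, Wang p the
upper tail of $W$ — which reproduces all published p-values for the Xeloda
worked example and removes the ambiguity.

**The ratio test** refers $\hat z = 1 - \hat m/\hat h$ to the law of
$r(a+X)/(b+Y)+1$ with $a = -(1-\delta_0)b/r$ at the null boundary. Its
p-value is computed directly as $1 - G(\hat z)$ from the integrated CDF
rather than by comparing $\hat z$ to a computed quantile: this avoids
stacking root-finding error on top of quadrature error. When $b$ and $r$
are unknown they are replaced by the plug-in estimates
$\hat b = \hat h/\sigma_H$, $\hat r = \sigma_{NI}/\sigma_H$, which is what
reproduces the published Xeloda analysis.

**The GPV test** eliminates the nuisance parameters by generalized
pivotal quantities. For one normal arm with observed mean $\bar x$,
variance $s^2$ and size $n$,

$$R_\mu = \bar x - Z\sqrt{\frac{(n-1)s^2}{nU}},
  \quad Z \sim N(0,1),\ U \sim \chi^2_{n-1},$$

has a parameter-free distribution and observed value $\mu$; the ratio
$R_{NI}/R_H$ inherits both properties for $\mu_{NI}/\mu_H$. The
generalized p-value is estimated from $M$ Monte Carlo draws as the
fraction of ratio draws at or above $1-\delta_0$.

### Tail direction of the GPV estimator

The source literature prints the estimator as a *lower*-tail frequency
$\sum_m I(T_m \le 1-\delta_0)/M$ while simultaneously rejecting for
*small* p and reporting tiny p-values for data whose observed retention
far exceeds $\delta_0$. Those three statements are mutually inconsistent,
so a direction had to be chosen. The package uses the upper-tail
frequency $p = \#\{R_{NI}/R_H \ge 1-\delta_0\}/M$: under
$H_0\colon \mu_{NI}/\mu_H \ge 1-\delta_0$, a small upper-tail mass at the
boundary is evidence against the null, this direction reproduces the
published type-I-error calibration (rates near 0.025 at the boundary),
and it produces the published qualitative behaviour on the worked example
(p near zero when the observed retention is far above $\delta_0$). Ties
at the boundary count toward the tail, and infinite draws from
denominator-GPQ zero crossings are retained ($+\infty$ in the tail,
$-\infty$ not): the ratio GPQ genuinely has heavy tails when the
historical effect is weak, and trimming would bias p toward rejection.

## Tunable parameters

* `delta0` — the retention fraction under test; 0.5 by default (the
  "retain at least half the control effect" convention). Unitless.
* `alpha` — one-sided level, default 0.025, the usual regulatory
  one-sided boundary.
* `M` / `gpq_draws` — GPQ draws per test, default 10000. The Monte Carlo
  SE of p is at most $0.5/\sqrt{M}$ (0.005 at the default).
* `seed` — every stochastic entry point takes one integer seed; the four
  GPQ streams ($Z_H, U_H, Z_{NI}, U_{NI}$), per-replicate seeds and
  per-cell grid seeds are derived from it by a fixed integer hash, so any
  cell can be reproduced in isolation.

## Numerical choices

The ratio-of-normals CDF integrates the normal density of the denominator
against the conditional normal tail of the numerator. The integral is
truncated at ten denominator standard deviations (normal mass beyond is
below 1e-23, negligible against the 1e-8 accuracy target) and split at
the denominator's sign change and at the inner CDF's transition point, so
adaptive quadrature never straddles a kink. Quantiles use an expanding
bracket started at $1 \pm 50r(1+|a|)/(1+|b|)$ — fixed brackets are unsafe
under Cauchy-type tails — followed by root refinement to 1e-10 in
probability. Degenerate inputs are handled explicitly: zero-variance arms
give point-mass GPQs, a zero historical estimate is a hard error for the
ratio-scale tests (the retention ratio is undefined), and `±Inf`
quantile arguments return the CDF limits.

## What the simulation generator emulates

`simulate_summary_tests()` draws estimator-level summaries — one
$N(\mu_{NI}, \sigma_{NI}^2)$ and one $N(\mu_H, \sigma_H^2)$ pair per
replicate with the variances known — because that is exactly the model in
which the three summary tests are derived. The ratio test re-estimates
$\hat b$ from each replicate's $\hat h$ with $r$ known, mirroring
practice where the historical effect is estimated but the design SDs are
treated as known.

`simulate_gpv()` draws `n_h` and `n_ni` *observations* per replicate with
per-observation standard deviations $\sigma_H = \mu_H/b$ and
$\sigma_{NI} = \mu_H/(b/r)$. Whether those SDs are per-observation or
estimator-level is genuinely underdetermined in the source description;
the per-observation reading was adopted because a closed-form Wald
approximation to the test's power under that reading (normal tail at
$z_{1-\alpha} - (\mu_H(1-\delta_0)-\mu_{NI})/\sqrt{\sigma_{NI}^2/n +
(1-\delta_0)^2\sigma_H^2/n}$) lands within a few points of the published
power surface (about 0.23/0.49/0.69 for $n=30$ at $b/r = 2/4/8$), while
the estimator-level reading predicts power an order of magnitude lower.
The default design values ($\mu_H = 0.24$, $n = 30$, 10000 replicates,
10000 GPQ draws, $\alpha = 0.025$, $\delta_1 = 0.625$ for power) are the
study conditions themselves, not knobs.

The generator emulates clean, independent, exactly normal samples with
known design parameters. It does not emulate the features of real NI
programmes: survival-endpoint estimates with censoring-driven standard
errors, between-trial heterogeneity in the historical meta-analysis,
violations of constancy, or correlated arms. Passing the simulation
checks therefore demonstrates correctness of the inferential machinery
under its stated model, not robustness to those departures.

The packaged test suite exercises the same machinery at reduced Monte
Carlo sizes chosen as a sensible desk-scale default — 2000 replicates
with 2000 GPQ draws for calibration and power checks, with tolerance
bands widened to three binomial standard errors at those sizes — while
`scripts/acceptance.R` runs the full 10000 × 10000 design.

## Design decisions in the data surface

The worked-example table recomputes every derived column
($\hat b, \hat r, \hat\delta$) from each row's own summary statistics
rather than carrying published rounded values forward; the
8-historical-trial rows' published $\hat\delta$ column appears to
duplicate the 10-trial values, and recomputation from the row's own
$\hat h$ is both self-consistent and what reproduces the published
ratio-test p-values for those rows.

The GPV test is deliberately absent from the summary-statistics surface
(`ni_test()` and the CLI refuse it there with an explanatory error): the
GPQ construction needs per-arm sample sizes and variances, which summary
rows do not carry, and fabricating them would silently change the test.
The published GPV p-values for the Xeloda example depend on per-arm
sample sizes that are not printed, so the package does not attempt to
reproduce that column.

## Limitations

* Normality of both arms is essential; the GPQ algebra does not transfer
  to other models, and no non-normal extension is provided.
* The method estimates p-values by Monte Carlo, so it is less suited to
  sample-size planning, where closed-form power is wanted.
* Wang's test inherits its published form; for $\hat h < 0$ its
  equivalence with Rothmann's test breaks down and neither is meaningful
  as a retention test.
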