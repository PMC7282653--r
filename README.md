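# fracret

Fraction-retention non-inferiority testing on the ratio of mean
differences, with a generalized p-value (GPV) test alongside the three
classical summary-statistics tests.

## The problem

A non-inferiority (NI) trial compares a new treatment `T` with an active
control `C` when a placebo arm `P` would be unethical. The regulatory
question is a **fraction retention** hypothesis: does the new treatment
retain at least a fraction `δ₀` of the control's effect over placebo?
Writing `θ₁ = T − P` for the new treatment's effect and `θ₂ = C − P` for
the control's effect (estimated from historical placebo-controlled trials,
under the constancy assumption), the hypotheses are

    H₀: δ ≤ δ₀   vs   H₁: δ > δ₀,    δ = θ₁ / θ₂.

The data are two independent normal summaries: the NI trial's
treatment-vs-control difference (mean `μ_NI`, SD `σ_NI`) and the
historical control-vs-placebo difference (mean `μ_H = θ₂`, SD `σ_H`).
Because `δ` is a ratio, every test must handle the nuisance parameters in
the denominator; the package implements four:

* **Rothmann's test** — a standardized linear contrast,
  `Z_R = (μ̂_NI − (1 − δ₀) μ̂_H) / √(σ²_NI + (1 − δ₀)² σ²_H)`, referred to
  the standard normal (lower tail).
* **Wang's test** — the asymptotic-normality form on the ratio scale;
  algebraically identical to Rothmann's test whenever `μ̂_H > 0`.
* **The ratio test** — the plug-in retention estimate
  `ẑ = 1 − μ̂_NI / μ̂_H` referred to its exact null law, the "Cauchy-like"
  distribution of `r(a + X)/(b + Y) + 1` for independent standard normals
  `X, Y` (Marsaglia's ratio-of-normals after a linear transformation),
  with `b = θ₂/σ_H`, `r = σ_NI/σ_H` and null boundary
  `a = −(1 − δ₀) b / r`. The CDF is computed by one-dimensional adaptive
  quadrature to 1e−8 (`pcauchy_like()`, `qcauchy_like()`).
* **The GPV test** — the package's centrepiece. From raw per-arm
  observations it builds generalized pivotal quantities for each mean,
  `R_μ = x̄ − Z √((n−1)s²/(nU))` with `Z ~ N(0,1)` and `U ~ χ²(n−1)`, takes
  their ratio `R_NI / R_H`, and estimates the generalized p-value as the
  fraction of `M` Monte Carlo ratio draws at or above `1 − δ₀`. It is
  exact-in-construction under heteroscedasticity and needs no asymptotics.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods, `autoplot()` for results, and a `fracret` command-line
script (in `exec/`) over the same functions.

## Worked example: the Xeloda trials

The packaged summaries (`xeloda_summary()`, also
`inst/extdata/xeloda.csv`) are the two Xeloda-vs-5-FU/LV colorectal
cancer trials and their pooled analysis, paired with two meta-analyses of
the historical 5-FU/LV effect (10 trials: 0.2341, SE 0.0750; 8 trials:
0.2398, SE 0.0593). The question: does Xeloda retain ≥ 50% of the
5-FU/LV effect?

```r
library(fracret)
xeloda_summary() |> ni_test(delta0 = 0.5, alpha = 0.025)
#> # A tibble: 18 × 5   (selected columns)
#>    study_id method   statistic p_value reject
#>  1 S014695  rothmann     -1.28 0.101   FALSE
#>  2 S014796  rothmann     -2.13 0.0165  TRUE
#>  3 Pooled   rothmann     -2.23 0.0129  TRUE
#> ...
#> 13 S014695  ratio         1.02 0.0830  FALSE
#> 14 S014796  ratio         1.36 0.0140  TRUE
#> 15 Pooled   ratio         1.18 0.00623 TRUE
#> 16 S014695  ratio         1.02 0.0774  FALSE
#> 17 S014796  ratio         1.35 0.0110  TRUE
#> 18 Pooled   ratio         1.18 0.00441 TRUE
```

For the ratio test, `statistic` is the observed retention-complement
`ẑ = 1 − μ̂_NI/μ̂_H` (e.g. 1.18 for the pooled analysis: the point estimate
says Xeloda retains more than 100% of the control effect), and `p_value`
is the upper tail of the Cauchy-like null law — 0.0044 for the pooled
8-trial analysis, so 50% retention is established at one-sided 2.5%.
`estimate_b_r()` exposes the plug-in standardized effects
(`b̂ = 3.1213` and `4.0438` for the two meta-analyses).

With raw per-arm observations the GPV test applies:

```r
read_raw_samples("arms.csv") |> gpv_test(delta0 = 0.5, M = 10000, seed = 1)
```

Simulation machinery estimates size and power on seeded grids:

```r
type1_error_grid(methods = "gpv", n_reps = 2000, gpq_draws = 2000) |>
  run_grid(master_seed = 1) |>
  autoplot()
```

Or from a shell:

```sh
exec/fracret test --method all --input inst/extdata/xeloda.csv --delta0 0.5
exec/fracret simulate --study power --methods gpv --reps 2000 --seed 1
```

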