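---
title: "Monte Carlo power analysis for SNARC slope designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo power analysis for SNARC slope designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The SNARC effect (Spatial-Numerical Association of Response Codes) is the
observation that small numbers are responded to faster with the left hand
and large numbers faster with the right hand. The classical way to
quantify it in a single subject is the dRT slope method: for every number
magnitude, average the right-hand and left-hand reaction times across the
`k` repetitions of that number, take the right-minus-left difference
(dRT), and regress dRT on magnitude by ordinary least squares. The
regression slope, in ms per magnitude unit, is that subject's SNARC
effect; a slope of -5 means a one-unit increase in magnitude gives the
right hand a 5 ms advantage. A within-group effect is then tested by a
one-sample t-test of the slopes against zero (one-sided, in the negative
SNARC direction), and a group difference by an independent-samples t-test
on the two sets of slopes.

`snarcpower` answers the design question behind such studies: given a
plausible slope (or slope difference), a sample size `n`, a number of
repetitions per item `k`, and the intra-individual reaction-time
variability `sdR`, what is the probability that the study will detect the
effect? It does so by direct Monte Carlo simulation of whole experiments.

## The generative model

Each trial's reaction time follows a linear magnitude model with additive
trial noise:

$$RT_{right}(m) = \beta_0 + m \cdot sl/2 + e, \qquad
  RT_{left}(m)  = \beta_0 - m \cdot sl/2 + e',$$

so that the expected right-minus-left difference at magnitude $m$ is
$m \cdot sl$. The baseline $\beta_0$ (default 500 ms) is identical for
both hands and cancels exactly in the dRT difference — the package
asserts this invariance in its tests. Errors are independent across
trials, hands and magnitudes; there is no subject-level random slope, so
the between-subject variance of estimated slopes comes entirely from
trial noise. This is deliberate: it makes the simulated power a property
of the design parameters alone, and it admits a closed-form cross-check
(below).

**Trial noise.** Reaction times are right-skewed, so the error is a
shifted, rescaled lognormal: $e = s\,(L - E[L])$ with
$\log L \sim N(0, \sigma^2)$, $\sigma = 0.5$ by default ("logarithmic
compression"), and $s$ chosen so that $SD(e) = sdR$ exactly on the linear
scale. Hence $E[e] = 0$, $SD(e) = sdR$, positive skew, and a finite lower
bound at $-s\,E[L]$. A reasonable alternative reading of the noise
specification would scale the linear SD by $\sigma$ as well (i.e.
$SD(e) = 0.5\,sdR$); we adopted the linear-scale $SD(e) = sdR$
construction because only it reproduces the published effect-size
structure of this design space (see "Calibration" below), and because it
keeps the `sdR` parameter interpretable as the observed within-condition
SD in ms.

**Defaults.** Magnitudes 0–9 (ten points per regression; other stimulus
sets such as 1–9 without 5 are configurable), intercept 500 ms,
$\sigma = 0.5$. The factor grids mirror the ranges found across the
empirical literature: slopes $-7$ to $-1$ ms (differences 2–8 ms),
$n \in \{10, 20, 30, 40\}$, $k \in \{10, 20, 30, 40\}$,
$sdR \in \{75, 150, 225, 300\}$ ms.

## From trials to power

For one simulated experiment the pipeline is: simulate `n` subjects
(`simulate_sample()`), estimate one OLS slope per subject
(`sample_slopes()`), test (`one_sample_snarc_test()` one-sided against
zero, or `two_sample_slope_test()` pooled-variance two-sided for two
groups), and code significance as 1 iff $p < \alpha$ (strictly), at
$\alpha \in \{0.05, 0.01, 0.001\}$. A design cell's power is the
proportion of significant replications, with binomial Monte Carlo
standard error $\sqrt{p(1-p)/R}$.

`run_grid()` executes a full factorial sweep. The per-cell runners use a
vectorized path that consumes the random-number stream in exactly the
same order as the subject-by-subject generator (each subject draws
$2 \times |magnitudes| \times k$ errors in one block), and the tests
assert the two routes agree to floating-point precision. Two-group cells
realize a slope difference `sld` symmetrically as $\mp sld/2$ around a
configurable base; because the difference test is location-invariant,
the base does not affect power (also asserted).

**Seeding.** A single master seed fixes every number in every output.
Each cell receives a substream seed from a documented counter-based map
(`derive_cell_seed()`), so any cell can be re-run in isolation and
reproduce its column of the full run, and cells could be executed
concurrently without changing results.

**The analytic bridge.** Under the model, a per-subject slope estimate is
the true slope plus a weighted sum of error cell-means, with SD
$\sqrt{2\,sdR^2 / (k\,S_{xx})}$, where
$S_{xx} = \sum_m (m - \bar m)^2 = 82.5$ for magnitudes 0–9. One- and
two-sample power then follow the noncentral-t distribution. The error
cell-means are averages of $k \ge 10$ lognormal draws, so they are
near-Gaussian and the closed form is accurate; the test suite checks
Monte Carlo power against it within Monte Carlo error across cells
spanning the whole grid. The closed form is used only as an independent
oracle, never as the implementation.

## ANOVA on binary outcomes

To summarize which design parameters matter, `factorial_anova()` fits a
between-cells factorial ANOVA to the 0/1 significance outcomes (one row
per simulated experiment) with all interactions, reporting partial
$\eta^2 = SS_{effect}/(SS_{effect}+SS_{residual})$ and the conventional
size bands ($<0.01$ negligible, $\ge 0.01$ small, $\ge 0.06$ moderate,
$\ge 0.14$ large). Two deliberate choices:

- A *linear* ANOVA on binary responses is heteroscedastic by
  construction (cell variance $p(1-p)$ depends on the cell mean). We keep
  it because it is the established summary for this kind of simulation
  study and because with hundreds of replications per cell the F-tests
  are used descriptively (via $\eta^2$), not inferentially. A logistic
  alternative is out of scope.
- Because the design is balanced by construction, sums of squares are
  computed exactly from the cell-mean decomposition (marginal means with
  inclusion–exclusion), which is orthogonal — Types I/II/III coincide —
  and fast at hundreds of thousands of rows. The tests verify it against
  `aov()` to 1e-8 on toy designs.

## Calibration against the published design space

This design space has been mapped before; the published factorial
summary reports partial $\eta^2$ of roughly 0.40 (slope size), 0.06
(repetitions), 0.16 (intra-individual SD) and 0.07 (sample size) for the
one-group sweep, and 0.29 (slope difference), 0.24 (SD), 0.08
(repetitions), 0.09 (sample size) for the two-group sweep. An analytic
pilot (expected $\eta^2$ computed from the noncentral-t power surface)
reproduces all eight values within ±0.01 under the linear-scale
$SD(e) = sdR$ noise construction, and misses them badly under the
$0.5\,sdR$ alternative — this is the evidence behind the noise-model
choice above. `scripts/acceptance.R` recomputes the same quantities by
full simulation at 300 replications per cell.

## Problem sizes and numerical choices

- The reported sweeps use 256 cells × 300 replications (the package
  default is 1000); at 300 replications a cell's power has MC-SE at most
  0.029, and the $\eta^2$ of a 256-cell ANOVA is far more precise than
  that. The test suite uses 1000–5000 replications where a single cell's
  calibration is at stake (type-I rates, monotonicity, oracle checks).
- Significance uses the strict inequality $p < \alpha$.
- Degenerate inputs fail loudly: zero slope variance in a sample, fewer
  than 3 magnitude points, zero magnitude variance, unbalanced ANOVA
  input, `n = 1` slope sets.
- The one-sided test direction is fixed to the canonical negative SNARC;
  positive true slopes are not a supported alternative hypothesis.
- Memory: the vectorized generator draws in chunks of at most $2^{23}$
  values, so even 120-repetition, 50-subject cells stay small.

## What the simulations do and do not show

The generator emulates trial noise realistically (right-skewed, bounded
below) but deliberately omits features of real data: between-subject
slope heterogeneity, trial-order and sequence effects, error trials and
outlier-trimming pipelines, and any correlation between speed and slope.
Passing tests therefore certify the statistical machinery of the slope
method under its own assumptions — they do not certify that any
particular empirical study meets those assumptions. In real data,
between-subject slope variance adds to the denominator of the one-sample
test, so the simulated power is an upper bound for within-group
detection when such heterogeneity exists.

## A worked example

```{r, eval = FALSE}
library(snarcpower)

# the headline design question: 20 subjects per group, 20 repetitions,
# a 4 ms slope difference, low intra-individual variability
params <- sim_params(slope_a = -2, slope_b = 2, n = 20, k = 20, sdR = 75)
cell <- run_cell_two_group(params, replications = 1000, seed = 1)
power_estimate(cell, alpha = 0.05)

# a small one-group sweep and its power curves
spec <- power_grid_spec("one_group", slopes = c(-5, -3), n = c(10, 20),
                        k = c(10, 20, 30, 40), sdR = c(75, 150),
                        replications = 500, seed = 1)
res <- run_grid(spec)
plot_power(res$power)

# which design parameters drive power?
factorial_anova(res$outcomes, response = "sig_05")
```
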