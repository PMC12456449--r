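---
title: "Exact random-effects meta-analysis for rare events: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact random-effects meta-analysis for rare events: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rexmeta)
```

## The problem

Drug-safety and public-health meta-analyses routinely combine a handful of
two-arm studies in which the event of interest is rare: a few percent or
less, often with studies recording zero events in one or both arms.
Classical pooled estimators (Mantel–Haenszel, Peto, DerSimonian–Laird) rely
on asymptotics in the number of studies and on effect estimates that are
undefined for zero cells, forcing arbitrary continuity corrections or study
exclusions that can invert conclusions. `rexmeta` provides an inference
procedure whose coverage guarantee does not degrade as event rates, study
counts, or within-study sample sizes shrink, because every test it inverts
is calibrated against the exact finite-sample distribution of its statistic
by Monte Carlo.

## Model

For study $i$, arm $j$ ($j = 1$ treated, $j = 2$ control), the event count
is modelled as $Y_{ij} \sim \mathrm{Poisson}(N_{ij}\lambda_{ij})$, with
both the baseline rate $\lambda_{i2}$ and the log relative risk
$\xi_i = \log(\lambda_{i1}/\lambda_{i2})$ free to vary across studies.
Under the null, the study total $Y_{i\cdot} = Y_{i1} + Y_{i2}$ is
sufficient for the baseline rate, and conditioning on it gives

$$Y_{i1} \mid Y_{i\cdot} \sim
  \mathrm{Binomial}\!\big(Y_{i\cdot},\ \mathrm{expit}\{\xi_i + S_i\}\big),
  \qquad S_i = \log(N_{i1}/N_{i2}),$$

which removes the nuisance baseline rate entirely. A double-zero study has
$Y_{i\cdot} = 0$ and its conditional likelihood is constant — it carries no
information about the relative risk — so such studies are removed (and
counted) rather than "fixed" with continuity corrections. The package's
unit tests verify the conditional law against brute-force enumeration of
the joint two-Poisson distribution for small totals.

Inference targets the mean of the **treatment contrast**
$\pi_i = \mathrm{expit}(\xi_i) = \lambda_{i1}/(\lambda_{i1}+\lambda_{i2})$,
with $\pi_i \sim \mathrm{Beta}(\alpha_0, \beta_0)$ as the random-effects
law. The contrast is 0.5 under no effect and maps monotonically to the
relative risk $\pi/(1-\pi)$. In moment coordinates $\mu_0 =
\alpha_0/(\alpha_0+\beta_0)$ and $v_0 = \mu_0(1-\mu_0)/(\alpha_0+\beta_0+1)$,
the requirement $\alpha_0, \beta_0 \ge 1$ (unimodality) is

$$v_0 \le v_{\sup}(\mu_0) = \mu_0(1-\mu_0)\,
  \min\!\Big\{\tfrac{\mu_0}{1+\mu_0},\ \tfrac{1-\mu_0}{2-\mu_0}\Big\}.$$

Without it, Beta laws with tiny shapes degenerate to two-point mixtures:
`beta_limit_mass0(0.001, 0.004)` is 4/5, so a law with nominal mean 1/5
puts all six contrasts of a six-study meta-analysis essentially at zero
with probability $(4/5)^6 \approx 26\%$ — the mean would be uninterpretable
as a centre. The constraint closes at the boundary: the profile search
below deliberately evaluates at $v = v_{\sup}(\mu)$, where the smaller
shape equals 1, and `shape_from_moments()` clips roundoff to exactly 1
there.

## Estimators

The test statistic is a Wald quadratic in method-of-moments estimators,
chosen over likelihood-based alternatives because it is non-iterative —
it must be recomputed on every one of thousands of simulated datasets per
grid point. For balanced designs ($N_{i1} = N_{i2}$), $Y_{i1}\mid
Y_{i\cdot}$ is beta-binomial and

$$\hat\mu = K^{-1}\textstyle\sum_i Y_{i1}/Y_{i\cdot},$$

with the between-study variance estimated from the second moment using
continuity-corrected counts $\tilde Y_{i1} = Y_{i1} + 0.5$, $\tilde
Y_{i\cdot} = Y_{i\cdot} + 1$ and truncated at zero. The corrections (fixed
at the conventional 0.5/1, not configurable) keep every study informative
when $Y_{i\cdot} = 1$ and keep the variance estimate positive when all
events fall in one arm; they bias moments slightly but cannot affect
validity, because the identical pipeline is applied to observed and
simulated data. Corrected totals are used throughout the variance of
$\hat\mu$ for the same positivity reason.

Unbalanced studies are reduced to weighted mixtures of balanced ones by
hypergeometric resampling: the larger arm is notionally down-sampled to
the smaller arm's size, the retained event counts enumerated, and each
outcome weighted by its hypergeometric probability
(`resample_support()`). Outcomes that would turn the study double-zero are
dropped and the weights renormalised. Only the case "treated arm larger"
has a canonical published form; when the control arm is larger the package
mirrors it — the control events are enumerated, the treated count stays
fixed, and the contrast ratio is always treated/total. The weighted
estimators reduce *exactly* to the balanced ones when every support is a
singleton, which the tests assert to 1e−12. The double-zero
renormalisation biases the point estimator away from 0.5 in sparse
unbalanced data; this costs CI length, never coverage.

A degenerate corner exists: all events in one arm and zero estimated
heterogeneity give $\hat\mu(1-\hat\mu) = 0$ and a zero variance. The
variance term is floored at machine epsilon (with a warning), which leaves
exactness untouched since observed and simulated statistics are floored
alike.

## Exact test and confidence interval

For $H_0: \mu_0 = \mu$ the p-value at a nuisance value $v$ is estimated by
simulating `m` datasets from the conditional model at $(\mu, v)$ — holding
each study's total and offset fixed, so no double-zero can arise — and
taking the proportion of simulated statistics at least as large as the
observed one (ties count as extreme; the p-value lives on the $1/m$
lattice). The profile p-value $\sup_v p(\mu, v)$ is approximated by a
single evaluation at $v_{\sup}(\mu)$, justified by the empirical
first-order stochastic dominance of the statistic's upper tail in $v$; a
test for that dominance (with Monte-Carlo slack) is part of the suite.

`exact_ci()` inverts the family of profile tests on a grid of step `s`
(default 0.001 on the contrast scale):

1. **initialize** at asymptotic Wald bounds widened by 50% of their
   half-width (a safety factor chosen so the subsequent walk is short in
   either direction), snapped to the grid and clipped to $[s, 1-s]$; a
   degenerate variance starts the search at the point estimate's cell;
2. **iterate** outward (or inward when the initial bound is already
   rejected) in steps of `s` until the profile p-value crosses `alpha`;
3. **correct** by examining 10 further grid points beyond each provisional
   limit — because boundary profiling is an approximation — extending to
   the outermost accepted point. The correction extends outward only;
   inward p-values are retained in the diagnostics for audit.

Default `m = 2000` makes the p-value standard error near the 0.05
threshold about 0.005, which together with the grid step motivates
reporting endpoints to about ±0.01. Every grid point draws from a
substream seeded deterministically by (seed, grid index), so the entire
interval is bit-for-bit reproducible, invariant to study order (studies
are canonically sorted before sampling), and nested across confidence
levels on the same seed. An exhaustive search over a two-dimensional
$(\mu, v)$ grid would multiply the cost by the size of the $v$-grid; the
dominance shortcut plus the correction step is the package's accuracy/cost
compromise, and the diagnostics tibble records every evaluation so a full
$v$-grid audit can be scripted on demand.

## Simulation harness

`sim_setting()` / `generate_meta_dataset()` implement a Poisson–Gamma
mechanism: $\lambda_{i1} \sim \Gamma(\alpha_0, \alpha_0/r_0)$ and
$\lambda_{i2} \sim \Gamma(\beta_0, \alpha_0/r_0)$ share a rate so the
contrast is exactly $\mathrm{Beta}(\alpha_0, \beta_0)$, while the treated
arm's mean event rate is $r_0$ (default 0.01, with 0.03 as the higher-rate
variant) and the control arm's is $r_0\beta_0/\alpha_0$. Poisson counts
are truncated at the arm size to keep them interpretable as event counts;
at rates of a few percent truncation is negligible and a counter reports
it. Size pairs are resampled from any supplied table (the bundled
synthetic drug-safety table is the natural default) or drawn
synthetically: control arms log-uniform on [60, 700], treated arms larger
by a factor of 1, 1.6 or 2, echoing unequal randomisation.

`run_operating_characteristics()` measures rejection rate, coverage, CI
length and double-zero prevalence. The suite and the acceptance script run
it at a reduced scale chosen to keep the full check under a few seconds —
300 replicates with `m = 500` and 12 studies — which bounds the binomial
standard error of a 5% rejection rate at about 1.3 percentage points; the
full-factorial design (thousands of replicates, `m = 2000`, study counts
up to 96) is the documented long-running configuration users can request
through the `simulate` subcommand. Replicates that retain fewer than two
studies are counted and redrawn: the estimators are undefined there, and
the conditional argument makes the discarded replicates uninformative
about the contrast.

What the generator does *not* emulate: informative study sizes (size and
effect are drawn independently), person-time denominators, multi-arm
trials, or publication selection. Passing operating-characteristic tests
therefore demonstrate calibration under the stated mechanism, not
robustness to those features.

## Bundled data

The two example tables under `inst/extdata/` are **synthetic** stand-ins
built by `data-raw/make_fixtures.R` from this same Poisson–Gamma model:
a 48-study, two-endpoint drug-safety table (two large trials, forty
smaller ones with log-normal treated arms and frequent 2:1 randomisation,
six additional double-zero studies; 10 studies with no events on the first
endpoint and 25 on the second) and a 29-study prevention table with a
higher event rate and a strongly protective contrast (mean ≈ 0.19). They
exercise every code path — endpoint remapping, double-zero filtering at
scale, mixed imbalance directions — but analyses of them should not be
read as analyses of the real studies they are shaped after.

## Numerical choices and limitations

* `expit`/`logit` go through `plogis()`/`qlogis()`, which are stable in
  the extreme tails.
* Variances below 1e−10 sample the contrast as a point mass at $\mu$
  (the Beta sampler is unusable with shapes of order $10^{10}$); this is
  the correct weak limit.
* The grid search assumes the accepted region projects to an interval; a
  pathological initialization far outside it collapses to the point
  estimate's cell and is flagged (`no_grid_point_accepted`), and endpoints
  that hit $s$ or $1-s$ are flagged `clipped_at_grid_edge`.
* Monte-Carlo error can make an endpoint wander by a grid step or two at
  `m = 2000`; raise `m` for publication-grade intervals.
* Only two-arm count data are supported: no person-time/incidence-rate
  inputs and no comparator-method implementations (the harness's tidy
  output joins cleanly with, e.g., `metafor` results computed externally).
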