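---
title: "Estimating subnational under-five mortality from birth histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subnational under-five mortality from birth histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5msmooth)
```

## The estimation problem

Under-five mortality (U5M) — the probability that a live-born child dies
before exact age five, conventionally reported per 1000 live births — is
observed only indirectly, through birth histories collected from women aged
15–49 in household surveys and censuses. Two instruments dominate:

* **Complete birth histories (CBH)** record each child's birth date and, if
  applicable, age at death. They support *direct* life-table estimation.
* **Summary birth histories (SBH)** record only each woman's children ever
  born (CEB) and children dead (CD). They require *indirect* (Brass-type)
  conversion through externally calibrated regression coefficients.

A country assembles many such sources over decades, each covering different
administrative units, years, and instruments, each with its own sampling
noise and method-specific error. `u5msmooth` implements the full chain from
microdata to a single smoothed county-by-year mortality surface:

1. a synthetic birth-history generator, so every stage is testable without
   access-restricted microdata;
2. the direct synthetic-cohort estimator;
3. four indirect estimators (cohort and period, each indexed by maternal age
   or time since first birth) with a least-squares calibration routine;
4. a Bayesian spatio-temporal smoother fusing all estimates;
5. metrics for mortality-reduction targets and between-county inequality.

## Direct estimation

Each child's lived months under age five are allocated to six age segments
(month 0, months 1–11, and years 1, 2, 3, 4) and to two-year periods counted
back from the interview. With `D` deaths and `E` child-months of exposure in
segment *s*, the monthly death probability is `m_s = D_s / E_s` and

$$ q_5 = 1 - \prod_s (1 - m_s)^{w_s}, $$

with `w = (1, 11, 12, 12, 12, 12)` the segment widths. Conventions that the
package fixes (and that its brute-force test oracle shares):

* time is discretized to calendar months; ages are month differences. Months
  are the finest grain any of the estimators need.
* the death month counts as a full month of exposure, and a death in the
  interview month counts as observed (ties broken toward the death);
* periods are anchored at the interview month and counted backwards;
  each period is labelled with the calendar year of its central month;
* a period in which any segment has zero exposure is *flagged undefined*
  rather than reported as zero;
* by default, periods whose midpoint lies more than 25 years before the
  interview are dropped from `estimate_direct()`: so far back, only the
  children of women still aged under 50 are observable, so the series grows
  selective as well as sparse.

## Indirect estimation and calibration

The cohort conversion maps each 5-year group's proportion dead to U5M on the
logit scale:

$$ \mathrm{logit}(q_5) = \beta_{0i} + U + \beta_{1i}\,
   \mathrm{logit}(CD_i/CEB_i) + \beta_{2i}\,\overline{CEB}_i +
   \beta_{3i}\, r_1 + \beta_{4i}\, r_2 , $$

where \(\overline{CEB}_i\) is the mean parity of the group and
\(r_1 = P(15\!-\!19)/P(20\!-\!24)\), \(r_2 = P(20\!-\!24)/P(25\!-\!29)\) are
parity ratios proxying the timing of childbearing. Each group's estimate is
located `ref_offset` years before the interview. The period methods first
redistribute reported CEB and CD over single years before the survey using
empirical distributions of births and deaths, then convert each year's
proportion dead with a two-parameter regression; they reach back 25 years
where the cohort methods reach 18.

Published coefficient sets for these conversions are estimated on large
multi-country CBH corpora and are not reprinted anywhere usable; the package
therefore ships coefficients calibrated by `calibrate_coefficients()` on a
packaged *synthetic* corpus (30 surveys of 8000 women spanning true U5M
30–250 per 1000, `make_calibration_corpus()`), and any externally published
set can be dropped in via `read_coefficients()`. Calibration choices that
were genuinely open, and how they were settled:

* **Response.** Each regression's response is the logit of the *direct*
  estimate computed from the same simulated population, interpolated (on the
  logit scale) at the group's reference time. This mirrors how real
  coefficient sets are built: SBH-style summaries regressed on the
  CBH-derived truth.
* **Reference times.** The "years before the survey" offset of a
  cohort group is computed as the exposure-weighted mean years-before-
  interview of the group's under-five child-months, capped at 18 years.
  Classical time-location formulas would be an alternative; the
  exposure-weighted rule is self-calibrating and needs no extra model.
* **Death redistribution.** Deaths are redistributed by the dead child's
  *year of birth*, so each redistributed year forms a birth cohort whose
  proportion dead has a clean interpretation for the per-year regression.
* **Regional offset.** The corpus represents a single synthetic region, so
  the offset `U` is fixed at 0 and absorbed into the intercepts.
* **Parity ratios for TFB tables.** Time-since-first-birth tables carry no
  maternal-age parities, so the TFB regressions omit the ratio terms (their
  coefficients are stored as 0) rather than importing values from a table
  the estimator may not have.
* **Corpus design.** Mortality levels follow a grid (so the conversion is
  identified over the whole plausible range); fertility varies by a
  *shuffled* ±15% scale so that fertility regressors are not collinear with
  the level; the latent fields use a small innovation scale
  (`sigma2_S = 0.003` with `phi_t = 0.95`, i.e. a marginal logit SD near
  0.2) — mortality series that drift smoothly rather than oscillate, which
  is what national U5M trends look like. Groups with unusable CD (0 or
  equal to CEB) are skipped; a regression is fitted only where at least 10
  corpus surveys contribute.

On held-out synthetic surveys of 5000 women, the calibrated conversions
recover the truth with a mean absolute relative error around 5–7% for the
central cohorts (ages 20–34) and years 0–15 before the survey — the test
suite enforces 10%. The youngest cohort (15–19) and the most
recent period years are markedly noisier; they are kept (down-weighted
naturally by the smoother's heteroscedastic noise) rather than dropped.

## The spatio-temporal smoothing model

Every per-survey, per-method county-year estimate \(Q_{ijkt}\) enters

$$ \mathrm{logit}(Q_{ijkt}) = \alpha + S_{kt} + Z_{ijkt}, \qquad
   Z_{ijkt} \sim N(0,\; \tau^2_j / \log n_{ijkt}), $$

where `S` is a zero-mean Gaussian field over counties and years with
separable precision

$$ Q_S = \sigma_S^{-2} \, \big( Q_{\mathrm{AR1}}(\phi_t) \otimes
   (D - \rho_s W) \big), $$

`W` the county adjacency, `D` its degree matrix. Modelling decisions:

* **Proper CAR.** The spatial factor uses the proper CAR precision
  `D − ρW` with `ρ ∈ [0, 1)`, so the joint prior is proper and a dense
  Kronecker covariance oracle is well-defined for testing. The intrinsic
  CAR is the `ρ → 1` limit.
* **Noise direction.** Read literally, "variance is the product of the
  log-transformed sample size and a method factor" would give *larger*
  surveys *more* noise; the stated intent is weights proportional to
  `log n` (so a census with hundreds of thousands of women cannot swamp the
  surveys). The default is therefore `tau2 / log(n)`; the multiplicative
  reading remains available via `variance_model = "multiply"`. The natural
  logarithm is used and `n >= 3` is enforced at load so `log n > 1`.
* **Census sample size.** Women interviewed (not births) is the `n` carried
  by every estimate, for surveys and censuses alike.
* **Priors** (not stated by the source model): `alpha ~ N(0, 10^2)`;
  half-Normal(0, 5^2) on the process and method SDs;
  `rho_s ~ U(0,1)`, `phi_t ~ U(−1,1)`. Weakly informative at the scale of
  logit-mortality data; all overridable, and any parameter can be *pinned*
  via `smoother_priors(fixed = ...)`, which is how the closed-form Gaussian
  oracles in the test suite condition on known hyper-parameters.
* **Sampler.** The field `S` (jointly, all `K x T` cells) and the intercept
  are conjugate Gibbs updates; `sigma2_S`, `rho_s`, `phi_t` and the five
  `tau2_j` are random-walk Metropolis on transformed scales. Proposal
  scales adapt toward 20–40% acceptance during burn-in only and are frozen
  afterwards, preserving detailed balance for the retained samples. The
  default schedule (110,000 iterations, 10,000 burn-in, thin 10, i.e.
  10,000 retained samples) matches the source analysis; the test suite and
  acceptance script use a reduced 11,000/1,000/10 schedule, which the
  recovery experiments show is already well mixed at their problem sizes
  (9–12 counties, 20–49 years).
* **Prediction without data.** Years or counties with no observations are
  predicted from the process prior conditioned on their neighbours — the
  posterior of the jointly-updated field, with no noise term. This is how a
  surface extending back to 1965 is produced from surveys starting in 1989.
* **Degenerate inputs.** A disconnected graph triggers a warning and is
  fitted as independent blocks (an isolated node is an error: its proper
  CAR precision would be singular); estimates with `q5` outside (0,1) are
  errors; `n < 3` rows are rejected with a warning.

## What the synthetic generator does and does not emulate

`simulate_survey()` draws women uniformly aged 15–49 at interview, produces
births month-by-month from a 5-year age-specific fertility schedule
(default near a total fertility rate of 5.5), and kills each child according
to a piecewise-constant monthly hazard over the six age segments, scaled so
the child's probability of dying before age five equals the true surface
value for its county and birth year exactly. The default allocation of
deaths over segments, `(0.35, 0.30, 0.15, 0.10, 0.06, 0.04)`, declines with
age in the manner of model life tables; the within-five age pattern is a
documented stand-in, since the estimators themselves never assume one.
Deaths after the interview are censored to "alive"; a death in the
interview month counts as observed.

Deliberate simplifications, hence limits on what passing tests show about
real data: fertility is independent of mortality (no replacement or
spacing effects); no migration between counties; no HIV-type crisis
mortality concentrated in particular cohorts; no survey weights, cluster
designs, date heaping, or recall displacement. Censuses are represented as
SBH-only surveys with large `n`.

## Known limitations

* Posterior credible intervals are calibrated for the model's own error
  structure: on model-simulated data, 95% intervals cover the truth at
  93–96% in the recovery experiments. Estimates produced by the *real*
  estimator chain violate independence — the 25 period-method estimates
  from one survey-county share the same underlying SBH totals — so
  intervals on fully realistic pipelines are optimistic. This is a
  structural property of this model class (observations enter as
  conditionally independent given the field), worth remembering when
  reading the credible bands.
* The ARR uses discrete compounding, `1 − (end/start)^{1/Δt}` — with the
  published 2000 and 2013 national means this reproduces the published
  4.5% per year, where the continuous log form gives 4.6% — and the log
  form is available behind `form = "log"`.
* The Palma-style inequality ratio needs at least 10 units; group sizes
  round to the nearest integer (47 counties: top 19 over bottom 5).
* The World Summit for Children "and/or" rule is implemented as OR: either
  the level (≤ 70 per 1000 by 2000) or the one-third 1990–2000 reduction
  suffices. `margin_class` marks a missed goal as a near miss when the
  binding criterion is missed by at most 20% relative.
* Cross-validation holds out 10% within every survey-by-method stratum;
  strata under 10 observations are skipped with a warning, and an empty
  test set is an error.

## Problem sizes used by the shipped experiments

The packaged experiments are sized so that a complete run stays comfortable
on a single CPU: recovery and coverage studies use a 9-county lattice over
20 years with all five methods and the reduced MCMC schedule; the
end-to-end pipeline demonstration uses 12 counties over 49 years with three
household surveys and one census. Both scale linearly in retained samples
and cubically in `K x T` through the field update's Cholesky factorisation;
a 47-county, 49-year national run at the full 110,000-iteration schedule is
the same code, just longer.
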