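---
title: "Methods: sleep scoring, anticipation indices and lifespan statistics in damsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, anticipation indices and lifespan statistics in damsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`damsleep` analyses *Drosophila* activity-monitor (DAM) recordings for
behavioural-ageing experiments. This vignette documents the models and
procedures the package implements, the parameters that matter and their
defaults, the design decisions taken where several reasonable choices
existed, and what the synthetic-data generator does and does not emulate.

## Input model and alignment

A monitor file is tab-separated with one row per minute: a record index,
date (`D Mon YY`), time, a status code, six metadata columns, a
light-sensor flag, then one count column per infrared beam. The geometry is
fully described by a `beam_layout()` (tubes x beams-per-tube, where the
count columns start, and the column-to-(tube, beam) map), so the same
reader handles multibeam files (8 tubes x 15 beams), classic single-beam
files, and already-summed per-tube files. Because hardware dialects drift,
nothing about the column order is hard-coded beyond this configurable
default.

Three data-hygiene rules are applied at parse time:

* **Malformed rows** (wrong column count, unparseable stamps, negative or
  non-integer counts) abort with the offending line number — silent
  corruption of a run-length-based analysis is worse than a hard stop.
* **Clock gaps** up to 5 missing minutes (configurable) are repaired by
  inserting zero-count rows, keeping the minute grid contiguous so that
  run-length sleep logic stays well defined; longer gaps abort.
* **Status codes** outside the valid set (default `{1}`) flag the row;
  flagged rows are retained, and any fly whose analysis window contains a
  flagged row is excluded with a logged reason. This is conservative,
  visible, and reversible.

The analysis window starts at the first lights-on event after an
acclimation period (default 24 h) and spans a whole number of 24-h cycles —
48 h in a four-age design, 24 h in a two-age replicate design. Zeitgeber
time (ZT) is hours since lights-on; a minute is "day" iff its ZT lies in
`[0, photoperiod)` under the half-open convention, so the lights-on minute
belongs to the day and no minute is double-counted. With a 12:12 schedule
each cycle contributes exactly 720 day and 720 night minutes.

## Sleep scoring

Sleep is the standard activity-monitor proxy: **five or more consecutive
minutes with zero counts**. A bout is one maximal such run; runs shorter
than the threshold contribute nothing. Two boundary rules needed a
decision:

* **Window edges.** Zero-runs truncated by the window edge count as sleep
  if their within-window length reaches the threshold. There is no
  look-ahead outside the extracted window.
* **Phase boundaries.** Whether a bout spanning lights-off belongs to the
  day or the night is underdetermined. Default: **split at the boundary** —
  each phase receives its overlapped minutes and one bout tally, and the
  phase bout length is phase minutes / phase bouts. This is the only rule
  that conserves day + night = total for sleep minutes. The alternative
  (`boundary = "onset"`: attribute the whole bout to the phase where it
  started) is implemented because other analysis pipelines use it. The
  whole-day bout total counts each distinct bout once, so for a fly asleep
  all day the total is one 1440-min bout even though each phase tallies
  one.

Per fly and recording day the package reports activity (day/night/total
counts), sleep (minutes), bout number, mean bout length, and the two
anticipation indices; recording days are then averaged per fly, omitting
undefined days. Undefined values (bout length with no bouts, anticipation
with a zero denominator) propagate as `NA`, never as zero — zeros would
bias group means. Binned population traces (default 30-min bins, 48 per
cycle) average days within fly first, then report mean ± SEM across flies;
with a single fly the SEM is reported as 0 with a warning.

## Anticipation indices

Flies are crepuscular and, when clock function is intact, ramp up activity
*before* the light transitions. The index quantifies this as

$$\mathrm{AI} = \frac{\text{activity in the final } w_n \text{ h before the transition}}
                     {\text{activity in the final } w_d \text{ h before the transition}}$$

with defaults $w_n = 3$, $w_d = 6$ following the published convention; both
windows are configurable because conventions differ between labs. Morning
(dawn) anticipation uses the window before lights-on — the end of the night,
ZT 18–24 within each recording day; evening (dusk) uses ZT 6–12 before
lights-off. A flat profile gives exactly $w_n / w_d = 0.5$; all activity
concentrated in the final 3 h gives 1. The index is scale-free, which is
what makes it comparable across monitor generations with different count
sensitivities.

## Viability filter

Flies that die mid-recording would otherwise contribute spurious "sleep".
A fly is scored dead when it shows **fewer than 3 counts over the final
180 minutes** of the analysed window (both numbers configurable); dead
flies are excluded from every metric table and listed, with the tail count,
in the exclusion log. The boundary is inclusive: exactly 3 counts is alive.

## Survival statistics

Survival analysis uses one row per individual (vial-level tallies scored at
transfers should be expanded to individuals with the transfer day as event
time; the generator's `scoring_interval_days` emulates that granularity).

* **Kaplan–Meier**: the product-limit estimator; censored subjects leave
  the risk set without a step. With no censoring it equals the empirical
  survival function; with no deaths the curve is flat at 1.
* **Median lifespan**: the smallest observed event time with
  $S(t) \le 0.5$ (the common survival-software convention); undefined, with
  a warning, if the curve never reaches 0.5. Percent decrease is
  $100\,(m_{\mathrm{ref}} - m)/m_{\mathrm{ref}}$, sign-preserving.
* **Log-rank**: the k-group observed-minus-expected statistic over pooled
  death times with the hypergeometric covariance, $k-1$ degrees of freedom.
  It is invariant to time rescaling and group relabelling.
* **Cox proportional hazards**: Newton–Raphson maximisation of the partial
  likelihood with step-halving; the **Efron tie correction** is the default
  (matching the widely used R implementation; Breslow is available, and
  the two coincide on tie-free data). Standard errors come from the inverse
  observed information. The sex-by-strain interaction is tested by the
  likelihood-ratio statistic between `~ sex * strain` and `~ sex + strain`;
  the model includes both main effects, which is the standard full
  parameterisation when the interaction is the target. Non-convergence and
  singular information (e.g. complete separation) abort with diagnostics
  rather than returning unstable estimates; the score test at zero is
  retained because with a single binary covariate and no ties it equals the
  two-group log-rank statistic — a useful cross-module identity check.

## Group comparisons

* **Two-way ANOVA** (age x sex, typically stratified by strain) uses
  **Type II sums of squares**, computed as residual-sum-of-squares
  differences between nested least-squares fits, with F statistics against
  the full-model residual mean square. Type II is the standard marginal
  choice for the mildly unbalanced cell sizes these experiments produce
  (flies lost to the viability filter); on balanced designs it coincides
  with the sequential and definitional decompositions, which the tests
  verify.
* **Dunnett many-to-one comparisons** against the control age cohort use
  pooled-variance t statistics and family-wise adjusted p-values from the
  multivariate-t distribution of the contrast vector, with correlation
  $\rho_{ij} = \sqrt{n_i n_j / ((n_i + n_c)(n_j + n_c))}$. The tail
  probability is evaluated by **seed-controlled Monte Carlo** (default
  $10^5$ draws, Monte-Carlo standard error reported) rather than
  closed-form quadrature: the Monte-Carlo scheme is exact in distribution
  for arbitrary unbalanced correlation structures, and the balanced
  two-comparison case (correlation exactly 0.5) is verified against
  numerical quadrature in the tests. One family is formed per
  (strain, sex, measure, phase) panel, mirroring how such comparisons are
  reported per figure panel. A single comparison reduces exactly to the
  pooled two-sided t-test, and adjusted p-values are floored at the
  unadjusted value, since multiplicity can only increase them.
* **Bonferroni**: `min(1, m p)`, for the replicate two-age designs.

## The synthetic cohort generator

The generator is a first-class module: it produces DAM-dialect files and
lifespan tables with known ground truth, so every pipeline stage has a
recoverable target. It emulates, per fly:

* **Sleep/wake structure** as a discrete-time alternating-renewal process,
  matching the 1-minute sampling. Wake runs are geometric with per-phase
  means (defaults: day 40 min, night 10 min). Sleep runs are
  **threshold-shifted geometrics**: `min_sleep_run - 1 + Geometric`, with
  `min_sleep_run = 5` and per-phase means (day 15, night 30 min). The shift
  exists because of a scoring interaction: for a *plain* geometric law with
  mean 30, memorylessness makes the mean of runs clearing the 5-min
  threshold exactly 34 min, so the configured mean could never be recovered
  by the scoring rule to within 10%. With the floor, every generated sleep
  episode is scoreable and the configured mean *is* the expected scored
  bout length; sub-threshold quiescence still occurs naturally through
  zero Poisson counts during wake. Setting `min_sleep_run = 1` restores the
  plain geometric law. The night-consolidated defaults (long night sleep
  runs, short night wake runs) reproduce the qualitative sleep architecture
  of young flies.
* **Wake activity** as Poisson counts with intensity (counts/min) =
  baseline (2) + a post-transition startle burst (amplitude 4, exponential
  decay 20 min, capturing the masking response at both transitions) + a
  **linear anticipation ramp** over the 6 h before each transition (slope
  0.5 counts/min per hour). The linear ramp gives a closed-form expected
  index, $(3\lambda_0 + 13.5 s)/(6\lambda_0 + 18 s)$ for baseline
  $\lambda_0$ and slope $s$ — 0.5 at $s = 0$, strictly increasing in $s$ —
  which the recovery tests use. The startle bursts sit outside both index
  windows by construction, so they do not contaminate the ramp checks.
* **Group structure** via per-group multipliers on activity, ramp slope,
  sleep-run means and lifespan hazard; **dead flies** (counts cease at a
  drawn death minute at 30–60% of the recording, so the viability rule must
  catch them); **empty tubes** (all-zero, the hardware negative control);
  and multinomial splitting of each minute's count over the beams, which
  conserves totals exactly.
* **Lifespans** from a Gompertz hazard $a e^{bt}$ (defaults
  $a = 5\times10^{-4}$/day, $b = 0.15$/day, median ≈ 36 days — a realistic
  laboratory lifespan), sampled by inverse transform, with independent
  censoring (default rate 0.02) and an optional transfer-day
  discretisation. The closed-form median $\log(1 + b\log 2/a)/b$
  (exponential $\log 2/a$ at $b = 0$) anchors the recovery tests.

Each fly draws from its own named substream derived from the master seed,
so adding flies or groups never perturbs existing traces, and a fixed
configuration is byte-reproducible.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: there is no circadian oscillator (the intensity
profile is a fixed function of ZT, so free-running rhythms, phase drift and
period changes are out of scope); no positional dynamics along the tube or
beam-specific sensitivity; no inter-fly correlation (shared incubator
effects); and the sleep/wake process is time-homogeneous within each phase,
so it has no siesta ramping or sleep-pressure dynamics. Recovery results on
synthetic cohorts validate the *scoring arithmetic and statistical
machinery*, not the biological realism of any particular trace.

## Numerical choices and degenerate inputs

* Ratios with zero denominators (anticipation index, bout length with no
  bouts) are `NA`, excluded from group statistics, and counted in logs.
* The Cox Newton iteration requires the partial log-likelihood to increase
  at every accepted step (step-halving otherwise) and aborts after 25
  iterations or when the information matrix is singular.
* The log-rank covariance submatrix is inverted directly, falling back to
  a pseudo-inverse for degenerate fixtures (e.g. a single death time).
* ANOVA with (numerically) zero residual variance returns `NA` F statistics
  with a warning rather than infinities.
* All Monte-Carlo procedures take explicit seeds and restore the caller's
  RNG state; pipeline runs are deterministic given the manifest, which is
  hashed by file *content* so the hash is location-independent.

## Problem sizes used in the test suite

The suite validates at the scale of the experimental designs it mirrors:
monitors of 8 tubes x 15 beams; analysis windows of 48 h (2 recording days)
after 24 h acclimation; recovery cohorts of 32 flies per group; survival
cohorts of 150–500 individuals; null calibrations of 2,000 replicates for
the log-rank, ANOVA and Dunnett error rates; and 1,000 random traces for
the bout-scoring oracle check. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities at these sizes
from a user-supplied seed.

## Known limitations

* The monitor-file dialect is a configurable default, not a certified
  reimplementation of any particular acquisition-software version; files
  with exotic metadata layouts need an explicit `beam_layout()`.
* Phase-boundary bout splitting is a convention; pipelines that attribute
  by onset will report systematically different phase bout numbers on the
  same data (both conventions are available).
* The Dunnett adjustment is Monte-Carlo: adjusted p-values carry a
  reported simulation error (~0.001 at the default draw count) and require
  a seed for exact reproducibility.
* Mixed-effects or repeated-measures models are out of scope; recording
  days are averaged within fly before any group test, so day-to-day
  correlation is absorbed rather than modelled.
* The survival module targets right-censored single-event data; competing
  risks, frailty terms and time-varying covariates are not supported.
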