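---
title: "Processing AHCS spot samples: duration thresholds, agreement, and sampling requirements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing AHCS spot samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahcsflux)
```

## The measurement problem

Automated head chamber systems (AHCS; the GreenFeed unit is the common
example) estimate the daily gas flux of unrestrained cattle — CO2 and
CH4 emission and O2 consumption, all in g/d — by averaging many short
"spot samples" collected while an animal voluntarily visits a baited
unit. Each visit yields one flux measurement per gas, a duration, and
an airflow reading. Two preprocessing choices dominate the quality of
the resulting per-animal estimate:

1. **Which visits count.** Short visits capture the breath cloud
   incompletely and read systematically low, so a minimum visit
   duration (1, 2 or 3 min are all in circulation) is imposed before
   averaging.
2. **How many visits are enough.** The per-animal mean converges only
   slowly, so experiments must run long enough for every animal to
   accumulate a sufficient number of qualifying visits.

The package implements the full decision pipeline around these choices:
QC filtering, per-animal estimation under duration rules, a
method-agreement battery against a gold standard, threshold- and
range-stratified reports, and a random visit-subsampling experiment
that locates the smallest visit count per animal achieving "excellent"
agreement. A seeded synthetic cohort generator with known ground truth
makes every stage testable without access to any proprietary visit
table.

## Quality control

Two filters are applied in a fixed order, each counted against its own
input:

* **Airflow adequacy.** Visits with airflow below 26 L/s (the default
  `airflow_min`) are removed; below that flow the breath cloud is not
  captured completely. The boundary value is kept — removal is strictly
  below the minimum.
* **Infeasible fluxes.** A visit is removed when any present gas
  exceeds its ceiling: 20,000 g/d CO2, 15,000 g/d O2, 500 g/d CH4.
  Equality is kept; missing channels never trigger removal. Negative
  fluxes are retained (no lower bound is defensible a priori) with a
  warning.

A record violating both rules is claimed by the airflow stage. That
attribution is a convention — the alternative (flux first) changes only
which stage claims the record, never the output table, and the test
suite asserts exactly that invariance.

## Estimation under duration rules

A duration rule is either a threshold (`>= L` min) or a half-open range
(`[L, U)` min). The per-animal estimate is the arithmetic mean of the
gas over qualifying visits. A time-bin alternative is provided
(`time_bin_estimates()`): visits are grouped into eight 3-h clock-time
bins by their start time, within-bin means are averaged across
*occupied* bins. Empty bins are excluded rather than imputed; sparsely
occupied bins therefore carry full weight, which is the known weakness
of the approach, so per-animal occupied-bin counts are reported for
filtering. Bin membership uses the visit start time only — visits are
minutes long against 3-h bins, so splitting a visit across a boundary
would be noise, not signal.

`per_animal_summary()` computes visits per day with an inclusive
calendar-day span, (last visit date − first visit date) + 1, as the
denominator. Published tables rarely state their denominator; the
inclusive span is pinned here so the summaries are reproducible, and
the same per-animal span (over all visits) is used for every duration
rule.

## Agreement statistics

Candidate estimates are compared with the gold standard — each animal's
mean over *all* QC-passed visits of at least 3 min — using:

* Pearson's *r* (precision),
* Lin's concordance correlation coefficient (agreement),
  $$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$
* the bias correction factor $C_b = \mathrm{CCC}/r$ (accuracy:
  penalises location and scale shifts),
* RMSE expressed as a percent of the gold-standard mean.

The CCC uses population (divide-by-*n*) moments. This matters: with the
squared mean difference in the denominator, the $1/n$ and $1/(n-1)$
conventions give genuinely different values, and the original estimator
(and the reference implementations commonly used in this literature)
divide by *n*. The test suite checks the implementation against an
independent closed-form evaluation on a thousand random vectors at
1e-12, and asserts the $\mathrm{CCC} = r \times C_b$ factorisation
everywhere. When $|r| < 10^{-12}$, $C_b$ is reported as `NA` rather
than divided out. CCC at or above 0.90 is taken as "excellent
agreement" throughout; the cut is a parameter.

No confidence intervals are reported: the downstream decisions
(minimum visit counts) are made on point statistics, and the
subsampling replicates already expose the Monte Carlo spread.

## Threshold and range reports

`descriptive_by_threshold()` and `agreement_by_threshold()` produce,
per experiment and duration threshold, the cross-animal mean ± SD of
duration, visit counts and per-gas estimates, and the agreement battery
against the same experiment's gold standard. "Pooled" rows concatenate
animal-level estimate pairs across experiments into one unweighted
comparison — no weighting scheme is imposed, so every animal counts
once. `duration_range_report()` does the same for the seven disjoint
ranges (<1, [1,2), ..., [5,6), >=6 min), which partition the visits;
the partition is asserted in tests.

`percent_difference_summary()` and `study_days_required()` implement
the downstream arithmetic: per-group percent differences with the
reference group as denominator, averaged unweighted across groups, and
visit quotas converted to experiment days (reported raw and rounded
up). The package ships the published per-threshold and per-range
summary statistics of a four-experiment beef-steer compilation
(`reference_threshold_stats()`, `reference_range_stats()`) and
`reference_derived_percentages()` recomputes the headline
cross-experiment percentages from them; the acceptance tests pin those
recomputations to ±0.1 percentage points. One printed inconsistency is
deliberately not asserted: the published narrative gives −0.8% and
−1.0% for the CO2 [5,6) and >=6 ranges, while recomputation from the
same table's cells gives −0.37% and −5.09%; the other gases recompute
cleanly. The range table's O2 SD for >=6 min is carried verbatim but is
implausible (11,199 g/d against a mean of 5,367) and is never used in
any computation.

## The subsampling experiment

`run_grid()` crosses duration thresholds (default >=3, >=2, >=1 min)
with visit counts n = 5, 10, ..., 60 and, in each cell, re-estimates
every animal's fluxes from a uniform random subset of exactly n
qualifying visits, drawn **without replacement** — "randomly selected
visits" from an animal's record naturally means distinct visits.
Agreement with the never-subsampled gold standard is computed per cell;
`minimum_visits()` takes the replicate-mean CCC per (gas, threshold,
n) and reports the smallest n reaching the cut (first crossing), with
non-monotone CCC sequences flagged rather than silently resolved.

Design choices worth making explicit:

* **One animal set for the whole experiment.** Animals must carry at
  least `eligibility` (default: the largest n in the grid) qualifying
  visits under *every* threshold, and at least one gold visit. A set
  that varied across thresholds would confound threshold comparisons
  with animal-selection effects.
* **Common random numbers.** Cells at the same (n, replicate) share
  their RNG seed across thresholds, so between-threshold contrasts are
  not blurred by independent sampling noise. All cell seeds derive from
  the design seed once, making any cell independently reproducible.
* **Replicates.** The default is 100 replicate draws per cell with the
  decision taken on the replicate-mean CCC; `replicates = 1`
  reproduces a single-draw design.
* **The gold standard is always the full >=3-min record**, even when
  the candidate threshold is itself >=3 min — the candidate at small n
  is then a proper subset comparison.

## The synthetic cohort generator

`generate_cohort()` draws, per animal: true fluxes from truncated
normals (defaults CO2 9,860.5 ± 835.8, O2 6,706.4 ± 631.1, CH4
149.9 ± 33.0 g/d — the between-animal spread of a published 53-steer
feedlot cohort, the same study the subsampling experiment is calibrated
to); visit times from a trimodal diurnal mixture (morning 07:00,
afternoon 16:00, overnight 01:00, weights 0.45/0.40/0.15) thinned
greedily to a 4-h minimum inter-visit gap; durations from a truncated
log-normal; and observed fluxes
$$\text{obs} = \text{true} \times (1 + b_g(\text{dur})) \times (1 + \mathrm{CV}\,\varepsilon),$$
with $b_g$ the piecewise-constant per-range bias curve calibrated to
the published per-range shortfalls (e.g. sub-1-min visits capture only
30.5% of true CH4) and $\varepsilon$ standard normal, correlated across
gases (0.8 between CO2 and O2, 0.5 with CH4) because the three channels
share one breath-cloud capture. The bias is multiplicative because
fluxes are positive and the published shortfalls are percentages; that
form transfers the calibration across animals of different magnitude.

Numerical and design details:

* **Duration model.** Log-normal with mode 3.5 min (`meanlog =
  log(mode) + sdlog^2`, `sdlog = 1.2`), truncated to [0.2, 12] min by
  inverse-CDF (renormalisation, no boundary atoms). Under these
  defaults ~79% of visits are >= 3 min and ~3% are < 1 min. The shape
  reproduces the features the analyses depend on — a duration mode near
  3–4 min and non-trivial mass in every short range — but carries a
  heavier long-duration tail (~48% of visits >= 6 min) than field data,
  where sub-1-min aborted visits are far more common and long visits
  rarer. Range membership, not tail shape, drives every pipeline stage,
  so this is an accepted mismatch; it does mean all-visits estimates
  are dragged down by the biased >=6-min range as well as by short
  visits.
* **Visit rate.** 3.4 candidate visits per day; the 4-h gap and the
  clustering of candidates into diurnal peaks thin this to a realized
  ~2.1 accepted visits/day, i.e. ~87 visits per animal over the default
  42 d, of which ~68 are >= 3 min. The gap constraint is a hard
  invariant (tested), and realized rates are observable via
  `per_animal_summary()`.
* **Clean airflow is truncated at 26 L/s** (N(30, 2) otherwise), not at
  the 20 L/s support floor: planted low-airflow visits are drawn
  uniformly on [20, 26). This keeps "QC removes exactly the planted
  violations" an exact invariant of the generator, which the degenerate
  tests rely on.
* **Truth truncation.** True fluxes are truncated 3 SD below the mean,
  keeping them positive without visibly distorting the configured
  spread.
* **Free parameter.** The visit-level noise CV (0.15) has no published
  counterpart; the qualitative test properties are insensitive to it
  across roughly 0.10–0.25.

With noise, bias and planting all zeroed, the generator is exact:
every observation equals the animal's true flux, estimates equal truth
to machine precision, and the full pipeline returns CCC = 1, RMSE = 0.
The test suite uses this degenerate mode as its end-to-end oracle.

## What passing tests do and do not show

The qualitative acceptance properties — replicate-mean CCC rising with
n, stricter thresholds never needing more visits than relaxed ones,
all-visits CH4 biased low against truth while >=3-min CO2 stays within
±2% — are checked on 20 seeded default cohorts (53 animals, 42 d) with
30 subsampling replicates per grid cell; those sizes are the package's
chosen test scale and complete in about a minute. Passing them shows
the pipeline's internal consistency and its qualitative agreement with
the published findings *under the generator's assumptions*. It does not
certify absolute minimum-visit numbers for real herds: the generator's
within-animal visit-to-visit variance is a free parameter, and real
cohorts have more short visits, diet and weather structure, and
day-level drift that the generator deliberately omits. On the default
synthetic cohorts the minimum visit counts come out lower (5–20) than
the published 15–40, exactly because the default visit-level CV of 0.15
is mild; the orderings, not the absolute counts, are the transferable
result.

## Limitations

* Timestamps are naive local clock time: no time zones, no DST. Time
  bins mean clock bins.
* No mixed-model or propensity-weighted estimation; arithmetic and
  time-bin averaging only, as these are the methods under comparison.
* The reference tables are printed summaries, not raw data; nothing in
  the package attempts to reconstruct the four source experiments'
  absolute cell values.
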