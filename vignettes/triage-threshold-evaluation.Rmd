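---
title: "Evaluating multi-label radiograph triage scores: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-label radiograph triage scores: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagecut)
```

## The problem

A deep-learning triage system for chest radiographs emits, for every
patient, a probability score in $[0,1]$ for each of seven abnormality
entities: adenopathy, atelectasis, fracture, pleural effusion, pneumonia,
pneumothorax and tumor. A two-reader consensus provides binary
gold-standard labels per patient per entity. The clinical questions this
package operationalizes are:

1. How well does each score discriminate its entity, and which cutoff
   should convert it into a binary call?
2. What happens when all seven calls are read *simultaneously* for one
   patient — can completely negative patients be removed from the
   radiologist worklist, and at what risk of missed findings?
3. Do patient covariates (sex, age, number of findings, foreign material
   such as implanted devices) bias the scores away from the gold standard?

`triagecut` implements the full evaluation pipeline plus a synthetic
cohort generator calibrated to the published summary statistics of a
477-patient inpatient study, so every stage runs and is testable without
access to the original per-patient data (which were never deposited).

## Per-entity ROC and the two cutoff policies

The call convention is global and explicit: **a score is called positive
iff it is at or above the cutoff** (`score >= cutoff`). The empirical ROC
takes the distinct observed scores as candidate thresholds plus two
sentinels (0: everything positive; above-maximum: nothing positive);
nothing is interpolated, so every operating point is exactly attainable
and brute-force enumeration can verify the implementation.

AUC is the trapezoidal area over (1 − specificity, sensitivity), which
for this construction equals the Mann–Whitney two-sample rank statistic
with ties counted one half. The confidence interval uses DeLong's
placement-variance estimator in its midrank form; when either class has
fewer than 10 members the normal-scale interval is replaced by a
logit-transformed one so the bounds respect $[0,1]$. With perfect
separation the placement variance is zero and the interval collapses onto
the estimate rather than pretending to a width.

Two cutoff policies are provided:

* **Youden-optimal** — maximize $J = \text{sensitivity} +
  \text{specificity} - 1$ over all operating points. Ties are broken
  towards the *lowest* qualifying threshold, which favours sensitivity;
  in screening, false negatives carry the greater clinical risk.
* **Sensitivity-constrained** (default floor 0.95) — the largest
  threshold whose sensitivity still meets the floor, i.e. the
  maximal-specificity point subject to the constraint. Sensitivity 1 is
  always attainable at threshold 0, so the policy is total.

## Confusion algebra and the two averaging conventions

`derive_metrics()` computes sensitivity, specificity, PPV, NPV and FPR
from a confusion cell. A ratio with an empty denominator is reported as
`NA` with an explicit flag — empty cells are real at extreme cutoffs, and
a silent 0 would corrupt averages.

Cross-entity "average" columns in published evaluations mix two
conventions, sometimes within one table: the *arithmetic* mean of the
per-entity rates, and the *pooled* (micro-averaged) rate of the summed
counts. `average_across_entities()` implements both and every report
labels which one each figure uses; reproducing the reference tables
requires arithmetic averages for some cells (e.g. mean PPV 21.05%) and
pooled ones for others (e.g. average FPR 24.96%).

## Conservative combined reading and workload

For simultaneous reading of all seven entities, each patient receives
exactly one category, with a strict precedence:

1. `FN_missed` — any gold-positive entity called negative. A correct
   detection elsewhere does not rescue the patient: the missed finding
   would go unreviewed.
2. `FP_any` — no miss, but at least one false alarm (regardless of
   additional true positives): the patient needs human review anyway.
3. `TP_complete` — at least one finding, everything called correctly.
4. `TN_complete` — no findings, no calls.

This precedence is the only ordering consistent with the reference
study's printed category counts summing to its cohort size. Metrics on
these four counts use the *category-count* denominators — combined
sensitivity is `TP_complete / (TP_complete + FN_missed)`, not
`TP_complete / (all gold-positive patients)` — because that is how such
combined readings are reported; since the convention is non-standard, the
report also carries a clearly labelled companion sensitivity over all
gold-positive patients.

Workload reduction is the `TN_complete` share of the *whole cohort*
(those patients could be dropped from the worklist), with the share of
gold-negative patients reported alongside; the price is the `FN_missed`
share.

## Concordance regression

The dependent variable is the deviation of the score from the gold
standard, $|{\rm gold} - {\rm score}|$: the score itself for
gold-negative observations, one minus the score for gold-positive ones.
Larger is always worse, which makes the two published sign patterns
(male sex associated with higher scores among negatives, female sex with
lower scores among positives) expressible by one definition. Sex is
coded 0 = male, 1 = female.

Observations are stacked patient × entity (7 per patient) and fitted by
OLS on z-scored variables separately for the gold-negative and
gold-positive strata, so coefficients are standardized betas and, with a
single covariate, equal the sample correlation. Multimorbidity is the
patient's total count of gold-positive findings, not excluding the index
entity. Stacking ignores within-patient correlation, matching the usual
presentation of such analyses, but understates uncertainty; a
patient-clustered (sandwich) standard-error option is therefore provided.
Blockwise entry of covariate groups reports incremental $R^2$ per block.
Because the published analysis reports standardized betas and $R^2$ —
linear-model quantities — OLS on the deviation is the primary model; a
logistic variant (outcome: thresholded call disagrees with gold, given
per-entity cutoffs) is available as a clearly labelled alternative.

## The synthetic cohort generator

The generator reproduces, at its defaults, the published composition of
the reference cohort:

* **Gold labels with exact marginals.** 477 patients; per-entity positive
  counts (13, 34, 33, 66, 31, 6, 43) and the finding-multiplicity
  histogram (310/116/44/6/1 patients with 0–4 findings) are hit
  *exactly*, not in expectation: a greedy pass (patients by decreasing
  finding count, entities by remaining demand) builds a feasible binary
  matrix, and margin-preserving random 2×2 swaps shuffle away its
  structure. Exactness keeps small-cohort tests non-flaky and mirrors the
  fact that the study reports exact counts. For other cohort sizes both
  marginals are rescaled proportionally with largest-remainder repair.
* **Positive scores** are beta-distributed, fitted per entity to the
  published median and IQR. A two-parameter beta cannot in general match
  all three quantiles (the best joint fit misses by up to ~0.026 for
  atelectasis), so the fit matches the **median exactly** (one shape
  solved by root finding) and least-squares the quartiles, attaching a
  fit-quality attribute when the quartile misfit exceeds 1e-3. The
  median is the quantity the calibration checks target, so it is never
  traded off.
* **Negative scores** are truncated normals on $[0,1]$. The published
  mean/SD describe the *observed bounded* scores, so the generator solves
  for the pre-truncation location and scale whose truncated moments equal
  the targets (naive truncation would inflate low means by up to ~0.04).
* **Covariates**: sex 59.54% male, foreign material 40.04%, integer ages
  drawn normal (mean 61.4, SD 16.73) and clipped to 18–91, with +7.2
  years added to patients with at least one finding, reproducing the
  published positive-vs-negative mean-age contrast (≈68.6 vs 62.1). The
  published cohort-level mean (61.4) is arithmetically incompatible with
  those subgroup means at 35% prevalence; the generator keeps the
  subgroup contrast, which is what the regression consumes.
* **Effect injection** for parameter-recovery experiments: deviations are
  perturbed additively by standardized covariates scaled by the
  within-stratum deviation SD, clipped to $[0,1]$ and mapped back to
  scores, so each injected coefficient is recovered (up to small clipping
  attenuation) as the standardized beta of the stacked regression.

What the generator does **not** emulate: between-entity score
correlations within a patient (unpublished; entities are conditionally
independent given the label matrix), co-occurrence structure beyond the
multiplicity histogram, and any image-level phenomena. Passing tests
therefore demonstrate that the pipeline is correct and calibrated to the
published summaries — not that it would reproduce the original study's
per-entity cutoffs or AUC confidence intervals, which depend on the
unavailable raw scores.

## Numerical choices and test design

* All randomness flows from one seed; the whole pipeline is
  byte-deterministic given it (cohort CSVs serialize scores at 6
  decimals).
* Stochastic calibration tests use tolerances pre-computed from sampling
  error, not round numbers: positive-median checks at $n = 10{,}000$ use
  four asymptotic median standard errors $\left(2 f(q_{50})
  \sqrt{n_{\rm pos}}\right)^{-1}$ with the fitted density (entity
  prevalences make $n_{\rm pos}$ range from ~130 to ~1400, so a blanket
  tolerance would be either loose or flaky); negative-mean checks use
  0.01 ≈ 4 SE; binomial fractions use 3 SE.
* A standardized beta estimated from one default cohort (~3100 negative
  observations) has sampling SD ≈ 0.015, so recovery of injected effects
  (0.15 / 0.09 / −0.04) is asserted on replicate means: ±0.03 on a
  5-replicate mean, ±0.02 bias over 20 replicates with ≥85% CI coverage.
* Oracle tests run ≥1000 random small instances against exhaustive
  enumeration (ROC points, Mann–Whitney AUC, both cutoff policies) and
  re-derive patient categories exhaustively on generated cohorts.
* Problem sizes in the suite (cohorts of 30–10,000; 20 regression
  replicates) were chosen so the full suite exercises every stochastic
  claim at useful power while remaining quick to run.

## Known limitations

* The AUC confidence-interval method of the original evaluation is
  unknown (software default); DeLong is a defensible, distribution-free
  choice, but printed CIs are not expected to be recomputable either way.
* Whether the original regression stacked patient × entity observations
  or aggregated per patient is not stated; stacking is implemented as
  primary because the analysis is described as running "across all
  entities", and the cluster-robust option quantifies the cost of that
  reading.
* A patient with both a missed finding and a false alarm is assigned
  `FN_missed`; the published totals are consistent with this precedence
  but do not uniquely prove it.
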