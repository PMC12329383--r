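---
title: "Randomization tests and reliable change in multiple-baseline SCEDs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization tests and reliable change in multiple-baseline SCEDs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsced)
```

## The design and its data

A nonconcurrent multiple-baseline single-case experimental design (SCED)
measures each participant weekly through four phases: baseline (A, 4-6
weeks, length randomized per participant), intervention (B), intervention
with an add-on practice tool (B2; its start after 0, 3 or 6 sessions is the
second randomization), and a 3-week follow-up block (C) six months after
treatment ends. Extensive assessments at pretreatment, posttreatment and
follow-up (T0/T1/T2) sit outside the weekly grid. Because each participant
serves as their own control, the staggered, randomized baselines are what
license causal statements: a time-locked confound would have to hit every
participant at their individually randomized phase change.

The package stores everything in a long table (participant, measure, week,
phase, value) with explicit missingness; all downstream statistics use
complete-case handling per comparison, because partial completers remain
analyzable in the comparisons their data support. Week indexing is 0-based
from the first baseline measurement. Sessions are identified with weeks for
scheduling, which matches weekly coaching; a different session calendar can
be represented by supplying session records directly.

## The randomization test

For one participant, the effect of treatment on a weekly measure is
Cohen's *d*: the baseline-minus-intervention mean difference over the
pooled (n−1-weighted) SD, sign-oriented so therapeutic change is positive.
Inference compares the observed *d* with its distribution over random
rearrangements of that participant's own scores; with 1000 resamples the
one-sided p-value is the exceedance fraction, floored at 1/1000 so a p of
zero is never reported.

Two resampling schemes are exposed because "random samples drawn from the
individual scores" admits two readings. The default, `label_permutation`,
reassigns the pooled scores to pseudo-phases of the original sizes: it is
the classical permutation null and treats the phase labels as exchangeable
under H0. The alternative, `startpoint_shift`, moves the intervention start
point across the admissible weeks (at least two points per side) while
preserving the series order: it is the design-consistent null for a
randomized start point and is less sensitive to serial dependence. Both are
reported by the same interface; the per-participant inclusion rule (at
least two measurement points in each phase) is enforced by the comparison
constructor, and series that are constant within both phases raise a
degenerate-variance error rather than fabricating a p-value.

Two numerical details matter. Resampled splits in which both pseudo-phases
are constant are mapped to d\* = 0 when the means agree and ±Inf otherwise,
which totally orders every resample against the observed value. And the
observed reference value is computed through the same code path as the
resamples, so permutations that exactly reproduce the observed split count
as ties instead of falling on either side of floating-point noise — on
tie-heavy integer data this is the difference between matching and missing
the exhaustive-enumeration answer.

### Group-level combination

Under the group null hypothesis every participant's one-sided p-value is
Uniform(0,1), so their sum S over n participants follows the Irwin-Hall
distribution; the group p-value is its exact CDF at S, computed by the
alternating-sum polynomial (numerically dependable to n ≈ 50, far beyond
any realistic replication count; a normal approximation N(n/2, n/12) and a
Monte-Carlo variant are provided for cross-checking). This additive
combination weights all participants equally and is sensitive to many
moderately small p-values, which suits replicated single-case series better
than Fisher's product rule, whose log transform is dominated by a single
extreme p.

The test suite verifies the calibration chain end to end: Monte-Carlo
p-values against exhaustive enumeration on all instances small enough to
enumerate, type-I error of the whole per-participant test within
[0.03, 0.07] at nominal 0.05 under an independent-noise null, uniformity of
the combined group p by a Kolmogorov-Smirnov test, and the Irwin-Hall CDF
against 10^6-draw Monte-Carlo estimates. Under AR(1) serial dependence the
label-permutation null is misspecified and the test's type-I error
inflates as rho grows; weekly questionnaire data with strong
autocorrelation should prefer the start-point scheme. The inflation is a
property of the permutation null itself, not of this implementation.

## Reliable change and clinical range

Assessment changes use the Jacobson-Truax reliable change index,
RCI = (pre − post)/s_diff, positive for symptom decrease, with closed
thresholds (|RCI| ≥ 1.96 for the ECBI scales, 1.645 for the OBVL). The
instrument constants are supplied via configuration: defaults are
s_diff = 21.8 (ECBI Intensity) and 4.69 (ECBI Problem), calibrated against
published (raw score, RCI) pairs from a PCIT-VR study, with two published
cells excluded from calibration as print anomalies (they are inconsistent
with their own raw scores and are shipped verbatim in
`pcitvr_rci_published()` for comparison). No default s_diff is set for the
OBVL: the published OBVL indices imply mutually inconsistent
difference-score SDs (≈1.64-1.68, possibly respondent-specific norms), so
the package requires an explicit value rather than guessing one. Clinical
cutoffs default to raw 131 (ECBI Intensity, the raw equivalent of the
instrument's clinical T-range), raw 13 (ECBI Problem) and T = 60 (OBVL),
classifying strictly-below-cutoff scores as below-clinical.

## Timepoint contrasts

Group pre/post/follow-up comparisons use the exact Wilcoxon signed-rank
test. Because samples of fewer than a dozen pairs routinely contain tied
and zero differences, the null distribution of the positive-rank sum is
computed exactly by a convolution over the (doubled, hence integral)
midranks after dropping zeros — `stats::wilcox.test` abandons exactness in
precisely these cases, and is used as the cross-check on tie-free data.
Participants who dropped out of the intervention but stayed in the study
contribute to pretreatment aggregates only; fully dropped participants are
excluded throughout. Both the pooled and the paired Cohen's *d* are
reported for each contrast since they answer different questions and
diverge in small samples; neither is privileged.

## The VR session-difference analysis

To ask whether the next coded session looks better after home practice,
the package differences consecutive archived DPICS sessions that have at
least one VR practice logged in between. The positive-following composite
is capped at 30 before differencing — the mastery criterion totals 30
tagged skills, so growth beyond it is not clinically meaningful — while
negative leading is left uncapped, as no analogous ceiling exists for
verbalizations one is meant to eliminate. Pairs with an unarchived session
on either side are skipped, never interpolated. Totals of VR practice split
participants into low (≤6) and high (≥7) use groups at a configured
constant rather than a recomputed median, because the operational grouping
rule, not the sample median, is the quantity of interest.

## The synthetic generator

`simulate_dataset()` emulates the study conditions: 11 families,
two-parent probability 7/11 (expected ≈18 participants), weekly ECBI
Intensity around 150 (within-person SD 10), OBVL-K T-scores around 72
(SD 4), baseline positive following around 4 and negative leading around
30, staggered designs drawn by `assign_design()`, AR(1) Gaussian noise
(default rho 0.2), 10% weekly missingness, a 1%/week dropout hazard, and a
VR practice rate of 1.5/week once the add-on starts. Level changes
(ECBI −15 in B, a further −5 in B2; OBVL −4/−1) and slopes (positive
following +2/week toward a ceiling of 35, negative leading −2/week toward
a floor of 2) were chosen once to produce the moderate-to-large,
participant-variable effects typical of this literature. Within-person SDs
are stand-ins — single-case reports rarely publish them — and are labelled
as such. Two parents of a family share the child's ECBI series (both rate
the same child) but have independent stress and skill series, and share
one design randomization.

What passing tests on these data do show: the pipeline recovers injected
level changes, holds its nominal error rates under the stated noise model,
and respects every structural invariant (instrument ranges, no VR before
B2, validator-clean output). What they do not show: robustness to real
weekly data's non-Gaussian jumps, informative missingness (families miss
weeks when stress peaks), or floor/ceiling clustering — the generator's
missingness and dropout are independent of the outcome level by design.

## Problem sizes and numerical choices

Calibration checks run at sizes chosen to make their Monte-Carlo error
bars decisive: 2,000 replicate series (10 points per phase, 1000 resamples
each) for the type-I error, 500 replicates for power at an injected level
change of 2 within-person SDs (observed power well above 0.8), 5,000
replicates for the uniformity of the combined p, and 10^6 draws per n for
the Irwin-Hall comparison. Exhaustive enumeration backs the Monte-Carlo
test on every instance with at most 10 points. Ties in resampled effect
sizes are resolved with a relative tolerance of 1e-9 against the observed
value; the Irwin-Hall polynomial is evaluated in log space and clamped to
[0, 1]; the Wilcoxon convolution doubles midranks to stay in integer
arithmetic.

## Limitations

The per-participant p-value floor (1/1000) bounds attainable significance;
series with fewer than about five points per phase cannot reach p ≤ 0.05
under enumeration no matter how large the effect. The additive combination
assumes independent participants, which two parents rating the same child
strain; combining within-family first is a reasonable manual workaround.
The DPICS coder-agreement index is a transparent min/max count ratio, not
an interval-by-interval kappa, and should not be compared numerically
against agreement figures computed otherwise. Visual inspection — the
first-line SCED analysis — is supported only as annotated plot-data export
(`plot_data()`); the judgment itself is out of scope.
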