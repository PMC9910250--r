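---
title: "Methods: from sleep EEG to functional brain networks and trial endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sleep EEG to functional brain networks and trial endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepfbn)
```

## What the package computes

`sleepfbn` implements the quantitative core of a sleep-EEG endpoint
analysis for a two-arm longitudinal trial in children with cerebral
palsy, together with the regional gray-matter volumetry that accompanies
it. The chain is:

1. **Acquisition model.** Eight-channel sleep EEG (C3, C4, P3, P4, O1,
   O2, P7, P8; 10--20 system; Cz reference) sampled at 128 Hz, stored as
   EDF.
2. **Preprocessing.** Zero-phase band-pass filtering to 0.30--30 Hz and
   extraction of ten non-overlapping 15-s NREM-II analysis windows
   (1920 samples each).
3. **Network construction.** Per window, an 8-node weighted graph with
   edge weights `|r|`, the absolute Pearson correlation between channel
   traces; the ten per-window graphs are averaged element-wise into one
   functional brain network per subject and timepoint.
4. **Graph metrics.** Degree (D), clustering coefficient (C),
   characteristic path length (L), global efficiency (E), and brain
   network energy (BNE).
5. **Endpoint statistics.** Between-group, paired, longitudinal
   (repeated-measures) and categorical contrasts on metric, scale and
   volume tables, with a normality-gated choice between parametric and
   rank tests; plus a per-region paired analysis of gray-matter volume
   tables with percent changes.

Because no patient-level data are deposited with the trial, the package
ships seeded synthetic generators for all three data types, with known
ground truth. These generators are first-class, tested code: they define
the conditions under which every downstream property is verified.

## Conventions that needed a decision

Several methodological details are not pinned down by the published
description; the package fixes them as follows and exposes switches
where a sensitivity analysis is sensible.

**Edge weights are `|r|`, unthresholded.** Negative correlation is
treated as connectivity strength, matching the common display of graded
edge thickness. No threshold is applied by default; `fbn_threshold()`
and `fbn_binarize()` exist for sensitivity analyses.

**Aggregation order.** The ten per-segment adjacency matrices are
averaged first and the metrics computed once on the mean network (one
network per subject/timepoint). `pipeline_config(aggregate =
"metrics-per-segment")` computes metrics per window and averages those
instead; on smooth weighted graphs the two differ mainly for the
nonlinear metrics (C, L, E).

**Weighted-metric conventions.** Strength is the row sum of weights.
Clustering uses the geometric-mean triangle formulation on weights
normalized by the maximum weight (nodes with fewer than two neighbours
get 0). Path length uses edge distance `1/w`; L averages over reachable
ordered pairs and reports the unreachable fraction separately, while E
counts unreachable pairs as zero efficiency. These are the dominant
conventions in weighted brain-network analysis, and they make the binary
complete graph satisfy D = n-1, C = 1, L = 1, E = 1 simultaneously.

**Brain network energy.** Defined here as spectral graph energy: the sum
of absolute eigenvalues of the weight matrix. It is 0 exactly for the
empty graph and `2(n-1)` for the binary complete graph. Alternative
readings exist in the literature (e.g. Laplacian energy); the source
trial cites methodology that is not publicly reproduced, so the package
states its operational definition prominently rather than guessing
among variants. Tests cross-check the eigenvalue sum against an
independent singular-value computation.

**Filter realization.** Only corner frequencies are specified upstream.
The package uses two cascaded 4th-order Butterworth sections (high-pass
0.30 Hz, low-pass 30 Hz) applied forward-backward (`signal::filtfilt`),
because zero-phase filtering avoids phase distortion that would bias
Pearson correlations. Filtering is applied per channel after demeaning.
Start-up transients are confined to the recording edges; analysis
segments should be drawn from recordings at least as long as the
150 s the default segment policy requires. A deliberate consequence of
the 30 Hz corner: content exactly at the corner is attenuated by half
per pass, so repeated filtering is only idempotent (RMS change < 1%)
for signals whose power lies well inside the band.

**Sleep staging and artifacts.** Out of scope. Segments are taken from
supplied recordings by position (sequential tiling or seeded random
non-overlapping placement); no staging rule, re-referencing, or artifact
correction is applied beyond a finite-value check.

## The statistics plan

The test-selection rule mirrors common clinical reporting: Shapiro-Wilk
at alpha = 0.05 on every relevant vector (each group for independent
contrasts; the difference vector for paired contrasts). If all pass, the
parametric test is used (pooled-variance Student's t; paired t) and
descriptives are mean ± SD; otherwise the rank analogue (Mann-Whitney U;
Wilcoxon signed-rank) and median (Q1--Q3). Groups too small for
Shapiro-Wilk (n < 3) fall back to the rank test, since normality cannot
be certified. The chosen test is recorded in every result, all tests are
two-tailed at alpha = 0.05, and no multiple-testing correction is
applied across measures or regions (the result tables carry the number
of contrasts so readers can apply their own).

**Longitudinal engine.** One-way repeated-measures ANOVA on subjects
with complete data (complete-case analysis; no imputation). Sphericity
is handled by rescaling the F degrees of freedom with the Huynh-Feldt
epsilon by default. This was a genuine design choice: the
Greenhouse-Geisser estimate is strongly biased downward at the cohort
sizes this design targets (n around 14, five timepoints), which makes
the unconditional GG test materially conservative (empirical size about
0.035 at nominal 0.05 under a spherical null in our simulations, versus
about 0.047 for Huynh-Feldt, which also retains the correction's
protection when sphericity actually fails). Greenhouse-Geisser and
"none" remain available via the `sphericity` argument. With two
timepoints the engine reduces exactly to the paired t test (F = t²).

**Categorical engine.** Pearson's chi-squared without continuity
correction, so the statistic is the classical sum of (O-E)²/E. Fisher's
exact test is available (`exact = "always"` or the conventional
`exact = "auto"` gate at expected counts < 5), but it is not the
default: at the arm sizes this design targets (15 vs 10), *every* 2×k
table has a column total at most 12 and hence an expected count below 5,
so an automatic Fisher substitution would silently replace the
chi-squared test always and pay Fisher's conservatism with no
compensating benefit. The default instead flags low expected counts in
the result's notes. Neither choice escapes discreteness at these sizes:
exact enumeration of the 2×2 null (binary outcome, 15 vs 10) puts the
uncorrected chi-squared engine's true size at 0.0614 for every null
proportion and Fisher's at 0.035, so a nominal-0.05 categorical test
simply does not exist for a 25-subject two-arm table. The package
reports the exact size rather than a simulation estimate of it.

**Paired "rank-sum".** The rank test used for paired designs is the
Wilcoxon signed-rank test on differences (the rank-sum test is the
independent-samples procedure; for paired data signed-rank is the
standard reading).

**Between-group scale contrasts** use raw values at the timepoint (the
layout of the published endpoint tables), not change-from-baseline
scores.

## The synthetic generators

**EEG.** Channels are linear mixtures of independent band-limited
Gaussian sources plus white sensor noise. The mixing matrix is the
principal square root of the target correlation matrix `R = I + W`,
where `W` is the coupling matrix, so the noise-free Pearson correlation
between coupled channels equals the planted weight, and noise of
standard deviation sigma (relative to unit signal SD) shrinks it by
`1/(1+sigma²)`. Couplings that are not jointly realizable as a
correlation matrix are projected to the nearest valid one (eigenvalue
clipping plus unit-diagonal rescaling). Sources are synthesized in the
frequency domain with an NREM-II-like profile -- delta-dominant
(0.5--4 Hz, 55% of power) with theta (20%), alpha (10%), a 12--14 Hz
sigma/spindle band (10%) and a small beta tail (5%) -- so essentially
all signal power lies inside the 0.3--30 Hz analysis band before
filtering. The default output scale is 20 µV per unit SD. This model
reproduces exactly the feature the pipeline consumes (second-order
cross-channel structure) and none of the features it does not: there is
no sleep staging, no artifacts, no nonstationarity, and no
volume-conduction physics. Passing recovery tests therefore demonstrate
correctness of the estimation chain, not realism of scalp EEG.

**Scale tables.** A linear random-intercept model per measure:
`score = baseline_mean + b_i + delta * sigma_b + e`, with subject
intercept `b_i ~ N(0, sigma_b²)` inducing within-subject correlation,
residual `e ~ N(0, sigma_w²)`, and `delta` the planted standardized
shift for a (measure, timepoint, arm) cell (zero at baseline by
construction). Scores are truncated to each scale's valid range.
Defaults: 15 vs 10 subjects, timepoints baseline/1M/3M/6M/24M, the seven
scale endpoints with baseline means taken from the trial's printed
baseline columns, `sigma_b` = 15 and `sigma_w` = 5 score units --
values chosen once as representative of scales scored on 0--100-type
ranges with strong subject-level stability.

**Volume tables.** Nine AAL regions (occipital, fusiform, parietal,
angular, temporal-pole) with baseline means and SDs from the trial's
printed volumetry table, 9 paired subjects, follow-up =
baseline × (1 + planted fractional effect) + 2%-of-mean measurement
noise. A `TOTAL` pseudo-region is the regional sum plus a per-subject
remainder (untracked gray matter, mean chosen so the total matches the
printed total-volume mean) held constant across timepoints, so regional
and total analyses are mutually consistent.

## Numerical choices and degenerate inputs

* Correlation matrices are symmetrized (`(A + t(A))/2`) and clipped to
  `[0, 1]` before network construction to remove floating-point
  asymmetry; the network class enforces exact symmetry, an exactly zero
  diagonal, and finite weights in `[0, 1]`.
* Constant channels, too-few samples, all-zero or constant paired
  differences, empty count rows, fully disconnected networks, unpaired
  volume subjects, and unknown timepoint/region labels all raise typed
  errors (`sleepfbn_*` condition classes) rather than propagating NaN.
* Shortest paths use Floyd-Warshall (n = 8; exact, no tie-break issues
  since ties in path length do not affect L or E).
* All generators are pure functions of their seed; the pipeline derives
  one sub-seed per recording from the master seed, and every output
  carries the seed and a hash of the effective configuration.

## Problem sizes used in the shipped checks

The shipped test-suite and acceptance script verify the pipeline at
sizes chosen to estimate each quantity tightly while staying desk-scale:
oracle equivalence on 100 random 8-node graphs; connectivity recovery on
50 simulated recordings of 160 s (ten 15-s segments each) at
per-channel SNR 1; calibration of the continuous test engines on 2000
null simulations at trial-like sizes (15 vs 10; 14 paired; 14 × 5
repeated measures) and of the categorical engine by exact enumeration
of all 176 possible 2×2 tables; generator bias checks on 500 simulated
cohorts; end-to-end determinism on a 4-vs-3 cohort at two timepoints.

One verification subtlety is worth recording. Rank-correlation recovery
of a *sparse* planted coupling is intrinsically bounded: with 25 of the
28 channel pairs planted at exactly zero, midrank tie handling caps the
Spearman correlation against any tie-free estimate at about 0.54, a
ceiling the pipeline reaches (observed ≈ 0.537 across 50 seeds, i.e.
the three planted edges are essentially always ranked on top). The
tie-free, graded-coupling check is the informative one and achieves
rank correlation above 0.99 on average.

## Known limitations

* The EEG generator shares no waveform morphology with real sleep EEG
  (no spindle events, no K-complexes, no artifacts); it validates
  estimators, not preprocessing robustness.
* BNE follows the package's operational definition (spectral graph
  energy); if the upstream analysis used a different energy variant,
  absolute BNE values are not comparable, though group contrasts of a
  fixed definition remain meaningful.
* The longitudinal engine is a repeated-measures ANOVA; generalized
  linear mixed models are out of scope.
* The EDF layer covers continuous equal-rate 16-bit recordings (the
  format's common clinical case), not EDF+ annotations or variable-rate
  signals.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(n_treatment = 15, n_control = 10,
                       timepoints = c("baseline", "6M", "24M"),
                       coupling_scale = data.frame(
                         arm = "treatment", timepoint = c("6M", "24M"),
                         scale = c(0.85, 0.7)
                       ),
                       seed = 1)
res <- run_pipeline(cfg)
res$metrics
res$comparisons
autoplot(res)                       # metric trajectories by arm
autoplot(res$networks[["T01/6M"]])  # one subject's network
```
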