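---
title: "Beta-series connectivity and threshold-sweep network characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-series connectivity and threshold-sweep network characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betanet)
```

## The problem

Event-related memory-retrieval experiments often produce subtle, distributed
effects: single regions barely differ between conditions while the
*interaction structure* of the whole brain does. betanet implements the
beta-series correlation approach to task-state functional connectivity for
exactly this setting. The experimental design it targets is a
paired-associate retrieval test: items learned under three reminder
conditions — an incomplete cue reminder (`Rc`, which triggers
reconsolidation), a complete reminder (`Rw`, equivalent to retraining) and
no reminder (`Nr`) — are retrieved in the scanner, each item shown for 4 s
and followed by a 2 s response cue, with fillers interleaved and
inter-trial intervals drawn from a truncated Gaussian. Because raw subject
data for such studies are typically not deposited, the package ships a
synthetic-data generator that emulates the design end to end, so every
stage is testable and the whole pipeline can be exercised from a single
seed.

## Single-trial estimation

Each picture trial is modeled as a separate event: its 4 s boxcar is
convolved with the canonical double-gamma hemodynamic response function
(peak delay 6 s, undershoot delay 16 s, unit dispersions,
peak:undershoot ratio 6, 32 s support — the conventional parameterization,
since only "canonical" is specified) and sampled at scan times. Response
cues are pooled per condition, filler pictures and filler cues are pooled,
and the inter-trial pauses are pooled into a baseline regressor; six
head-movement parameters can be appended as nuisance columns. This
reproduces, at the condition level, the nine-regressor structure of the
original design.

Two single-trial estimators are available:

* **LS-A** (default): one GLM containing all trial regressors
  simultaneously; ordinary least squares per region. This is the simpler
  reading of "each picture as a separate event", and it recovers noiseless
  planted amplitudes exactly (to solver precision), which the tests verify.
* **LS-S** (`mode = "lss"`): one GLM per trial, with remaining trials
  pooled per condition. Note that LS-S is intrinsically biased when trial
  amplitudes vary within a condition — the pooled regressors cannot absorb
  per-trial spread — so exactness can only be expected for homogeneous
  amplitudes. It is provided for designs with heavy regressor overlap,
  where its variance advantage can outweigh that bias.

The design includes both a pause regressor and an intercept. Because
events and pauses tile the run, their convolved columns sum to a
near-constant mid-run, so the design is ill-conditioned but not singular
(condition numbers around a few hundred in the default design); the QR
solver handles this, exact rank deficiency is detected and reported with
the offending columns named, and the beta-value *contrast*
(condition − pause) is stable in any case.

Region beta-values are condition-mean trial betas minus the pause-baseline
beta. Thirty retrieval-related regions are pooled into seven bilateral
regions (hippocampus; parahippocampus; prefrontal; parietal; temporal;
posterior and anterior cingulum) by unweighted averaging — the neutral
choice where no weighting is specified. (Descriptions of this protocol
sometimes quote "32 ROIs", but the explicit grouping enumerates 15
bilateral pairs, i.e. 30 labels; the pooling map implements the explicit
list.)

## Band-pass filtering

A zero-phase Butterworth band-pass (default 0.01–0.25 Hz, order 4) can be
applied along the beta-series trial axis, treating the trial index as
uniformly sampled at 1 / (mean picture spacing). Two numerical points
matter:

* With ~12–14 s between pictures, the trial-axis Nyquist frequency
  (~0.04 Hz) is *below* the conventional 0.25 Hz upper edge. Rather than
  erroring on the standard band, the filter degrades to its high-pass part
  with a warning when the upper edge reaches Nyquist. (The same issue
  already exists at the scan level: 0.25 Hz exceeds the 0.2 Hz Nyquist of
  a 2.5 s TR.)
* The series is demeaned and reflection-padded to full length before the
  forward-backward pass, suppressing the slow high-pass end transient.
  Per-condition series of 12 trials are too short for an order-4
  zero-phase filter, so the pipeline filters the full trial-ordered series
  before splitting by condition; filtering is off by default in
  `run_pipeline()` and exposed via the config.

## Connectivity

For each condition, the Pearson correlation of every pair of regions'
beta series gives a symmetric association matrix `C = (c_ij)` (90 × 90 for
the default parcellation); zero-variance regions are set to `NA` with a
warning and excluded pairwise. The Fisher transform `z_ij = arctanh(c_ij)`
is applied after clipping `|c|` at `1 − 1e-7` so degenerate perfect
correlations stay finite. The group ("grand mean") matrix is the
elementwise *mean* of the subjects' z matrices. (Write-ups of this method
sometimes print the grand mean as a bare sum over participants; a sum
would make fixed downstream thresholds like 0.35 depend on the sample
size, so the mean is used.) Missing entries are excluded pairwise with
per-entry counts retained.

## Threshold sweep and graph measures

The grand-mean matrix is binarized at 6000 uniformly spaced thresholds
from its minimum off-diagonal entry to 0.6 (linear spacing, endpoints
inclusive; the grid is otherwise unspecified). An edge joins regions
`i, j` when `r_ij >= t` — ties included — and *nodes* are the regions with
at least one link; isolated regions are excluded from both averages, and
degree-1 nodes contribute local clustering 0.

* Average degree: `<k> = (1/n) Σ k_i` over listed nodes.
* Clustering: `C_i = 2 t_i / (k_i (k_i − 1))` (fraction of linked neighbor
  pairs), `C` = mean of `C_i` over listed nodes.

Both are implemented directly on adjacency matrices and verified against
brute-force enumeration and igraph. One subtlety: under the
nodes-with-links convention, `<k>` is guaranteed non-increasing in the
threshold only while the node set is stable — when isolated nodes drop
out of the average it can tick upward. The total link count is
non-increasing unconditionally. On the default synthetic cohorts the
graphs keep all 90 regions linked over the whole grid, so the familiar
monotone decay holds there.

## The random-graph null

Descriptions of this null in the literature are sometimes
self-contradictory — random graphs "with the same number of nodes and
links" *and* "probability of attachment 0.5" cannot both hold. The default is therefore the matched
ensemble G(n, m) (uniform graphs with exactly the observed node and link
counts), which is the property the comparison needs; the fixed-probability
ensemble G(n, p) is provided as a mode, and for it `E[C] = p` analytically,
which doubles as a calibration check (`p = 0.5` on 90 nodes gives mean C
within ±0.01 of 0.5 over 1000 replicates).

Per threshold, 1000 replicates (configurable) are drawn from one seeded
stream and the exceedance p-value uses the add-one Monte-Carlo convention
`p = (1 + #{C_null >= C_obs}) / (R + 1)`, so p is never zero and ties count
against significance. The comparison is one-sided (exceedance) by default
— the shaded significance regions in this literature reflect observed
clustering *above* random — with a two-sided option. The significance
flag uses α = 0.01.

## Statistics

Retention is correct responses at testing minus training, per subject and
condition. The behavioral model is a mixed repeated-measures ANOVA
(condition within, evaluation time between), fitted by `stats::aov` with
an `Error(subject/condition)` stratum; partial eta squared is
`SS_effect / (SS_effect + SS_error)` within the effect's stratum.
Sphericity is tested with Mauchly's test (on the multivariate model) and,
when rejected at α = 0.05, Greenhouse–Geisser-corrected degrees of freedom
are reported; epsilon comes from the classical element-means formula on
the double-centered pooled within-group covariance, bounded in
`[1/(k−1), 1]`, and is cross-checked in the tests against the eigenvalue
formula. Post-hocs are paired t-tests with Bonferroni correction (m = 3).

The per-region one-way ANOVA on pooled beta-values defaults to the
within-subject (repeated-measures) error structure, matching "condition as
the within-subjects factor"; a between-subjects error structure is
available because some reported degrees of freedom (e.g. F(2, 39) with 14
subjects) imply it. Results are labeled with the structure used.

## What the generator emulates — and what it does not

`simulate_cohort()` produces, per subject, a testing-session event table
(36 items in 3 balanced conditions, 12 fillers interleaved, 4 s pictures,
2 s cues, ITI ~ Gaussian(8, 1) truncated to [6, 10] s by rejection —
reconciling the stated bounds with the stated distribution) and a
region-level BOLD run: each trial draws a 90-vector of amplitudes from its
condition's multivariate normal, regions are organized in three blocks of
30, and the signal is the amplitude-weighted sum of HRF-convolved boxcars
plus white noise. Run length is derived from the design (the printed
volume count and session length are mutually inconsistent, so neither is
hard-coded). Filler amplitudes are fixed rather than random so that the
pooled filler regressor matches the forward model exactly and the
noiseless round trip is exact.

Default planted correlations (within/between block): Rc 0.70/0.38,
Rw 0.50/0.28, Nr 0.50/0.26, amplitude SD 1, noise SD 1. These were chosen
once, from the generative calculation, so that the default 14-subject
cohort qualitatively reproduces the published network ordering — Rc
densest with Rw ≈ Nr — and lands near the printed adjacency summaries at
the 0.35 threshold (⟨k⟩ ≈ 75 for Rc, ≈ 42–45 for Rw/Nr). Behavioral
defaults (training mean 9.4 of 12; testing means day-5 9.1/8.8/5.9,
day-15 8.4/5.4/2.4; SD 1.2, counts rounded and clipped) reproduce the
published qualitative post-hoc pattern: on day 5 Rc and Rw are
indistinguishable and both beat Nr; on day 15 all three conditions
separate.

The generator deliberately omits scanner artifacts, motion,
physiological noise, spatial structure within regions, and
autocorrelated noise. Passing tests therefore demonstrate correctness of
the estimators and the planted-parameter recovery path — not robustness
to real-data confounds, which the surrounding preprocessing (outside this
package's scope) is responsible for.

## Numerical choices

* Correlation clipping `clip_eps = 1e-7`; diagonal excluded everywhere.
* Thresholding uses `>=` (ties included), per the stated link definition.
* Add-one Monte-Carlo p-values; one seeded stream per sweep.
* OLS via QR; rank checks name collinear columns; an independent
  normal-equations solve is the test oracle.
* Degenerate ANOVA inputs (constant data) report F = 0, p = 1 rather than
  0/0.
* Regressor construction samples a 10 ms convolution grid, accurate to
  ~0.5% against a 1 ms reference.

## Problem sizes in the test suite

The suite exercises the study-scale configuration (90 regions, 36 + 12
trials, 14 subjects) where the property at stake needs it — e.g. sweep
contracts on the full 6000-threshold grid and condition dominance over a
600-threshold grid with 100-replicate nulls — and smaller
parameterizations (12-region, 4-item subjects; 30-node null calibrations
with 500 Monte-Carlo replicates) where the property is scale-free. These
sizes are the package's own choice of test design; the estimators
themselves carry no scale assumptions.

## Known limitations

* The beta-series method assumes trial amplitudes are separable by the
  GLM; with very short ITIs the trial regressors overlap heavily and LS-A
  variance grows (LS-S trades this for bias).
* Pairwise-complete grand means can mix different subject counts per
  entry when regions are degenerate in some subjects; counts are kept in
  the `n_used` attribute so downstream users can threshold on them.
* The mixed ANOVA assumes balanced condition cells; subjects with missing
  cells are rejected rather than imputed.
* `<k>`-monotonicity caveat above applies to sparse, fragmenting graphs.
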