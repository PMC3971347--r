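---
title: "Extracting time-specific transcriptional profiles of acute respiratory illness"
author: "ariprofiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting time-specific transcriptional profiles of acute respiratory illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ariprofiles)
```

# The problem

Acute respiratory illness (ARI, the "common cold") is the leading trigger
of asthma exacerbations. `ariprofiles` implements a longitudinal analysis
of nasal-mucosa expression over the course of ARI in four clinical groups
— healthy, allergic rhinitis, asthma without exacerbation (`AsmNoEx`) and
asthma with exacerbation (`AsmEx`) — sampled at an asymptomatic baseline
(`BL`) and on roughly days 2 and 6 of symptomatic illness (`D2`, `D6`).
The course is split into three transitions: **peak** (BL to D2),
**reduction** (D2 to D6) and **resolution** (D6 back to BL). The goal is
to extract, per group and transition, a ranked gene signature, and to
classify signature genes as *core* (all groups), *shared* (a strict
subset of groups) or *distinct* (one group only — the candidate
exacerbation-specific signature).

# The statistical model

## Blocked differential expression

Each gene's log2 intensity is modelled by a cell-means ANOVA over the
12 group-by-timepoint cells. Repeated samples from one subject are
correlated; we assume an equicorrelated (compound-symmetry) covariance
within subject and independence across subjects, and fit each gene by
generalized least squares after whitening with the block matrix
$R^{-1/2}$, where $R = (1-\rho) I + \rho J$ per subject. With $\rho = 0$
this is exactly OLS.

The consensus correlation $\rho$ is estimated once for all genes: per
gene, a method-of-moments estimate from the two-way (subject-by-time
within group) decomposition of the cell-means residuals,
$\hat\rho_g = \hat\sigma^2_b / (\hat\sigma^2_b + \hat\sigma^2_e)$ with
$E[\mathrm{MS}_\mathrm{subject}] = k\sigma^2_b + \sigma^2_e$, clamped to
$(-0.95, 0.99)$; then a 15% two-sided trimmed mean on the
$\tanh^{-1}$ scale, back-transformed. The trim makes the average robust
to the heavy tails of per-gene estimates at small subject counts; the
variance-stabilizing transform stops boundary estimates from dominating.

Moderated statistics follow the standard empirical-Bayes hierarchy: the
per-gene residual variances $s^2_g$ (with $d_g$ degrees of freedom) are
assumed scaled-$F$ around a prior $(d_0, s_0^2)$, estimated by matching
the mean and variance of $\log s^2_g$ through the digamma/trigamma
relations (with Newton inversion of the trigamma). The posterior variance
is $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ and
$\tilde t_g = b_g / (\tilde s_g \cdot v^{1/2}_g)$ is referred to a
$t_{d_0 + d_g}$ reference. When the dispersion of log variances is at or
below its theoretical minimum, $d_0$ is capped at $10^6$ (practically
infinite shrinkage). A log-posterior-odds B statistic with a fixed prior
DE proportion of 0.01 is reported for reference but never used for
selection.

The three time contrasts (D2−BL, D6−D2, D6−BL) are time main effects
averaged with equal weight over the four groups — the design pools groups
because per-group tests at these sample sizes are underpowered. P-values
are Holm-adjusted within each contrast family (all genes of one
contrast); the **ARI gene set** is the union over the three contrasts of
genes with Holm-adjusted p below $\alpha = 0.05$, with deliberately *no*
fold-change filter.

## PCA signatures

All PCAs are covariance-matrix PCAs of the ARI genes: genes are
variables, samples observations, each gene centered but not scaled,
computed by SVD of the centered matrix (so 5,000 genes by 16 samples is
fine). PC sign is arbitrary, so PC1 is *oriented*: the mean PC1 score of
the symptomatic time point of the transition (D2 for peak and reduction,
D6 for resolution) is made nonnegative. Per focal time point the profile
direction follows the sign of the focal samples' mean PC1 score:
positive focal means take the $N = 100$ most positive loadings, negative
means the 100 most negative. Loading ties (essentially impossible on
real data, but possible on constructed fixtures) break lexicographically
by gene identifier so output is deterministic. When a focal mean is
within $10^{-9}$ of zero the direction defaults to positive with a
warning.

Membership classification is plain set arithmetic over the per-group
profiles, emitting the full Venn region table (which subsumes any
pairwise or k-way comparison count): `core` in all groups,
`distinct:<g>` in exactly one, `shared:<subset>` otherwise.

Cluster separation along PC1 is tested by a paired t-test when subjects
are matched across the two time points, and a two-sided Mann-Whitney U
otherwise. Identical paired score vectors return t = 0, p = 1; constant
*nonzero* paired differences are a degenerate-test error (zero variance
with a real shift is not testable).

## Kinetics

Per-gene trajectories are the mean log2 intensity per group-by-timepoint
cell; for plotting-style comparisons they are min-max scaled jointly over
all cells so each gene attains exactly 0 and exactly 1. Constant genes
map to 0.5 and are flagged rather than erroring, so kinetics tables stay
drawable. Transition fold changes are later-minus-earlier means
(subject-matched when pairing is complete, cell means otherwise), and
fold-change profiles are clustered by UPGMA (unweighted average linkage,
Euclidean distance), serialized as a portable merge table.

## Clinical statistics

The a priori exacerbation adjudicator is a pure rule: criterion 1 is
care-seeking or corticosteroid escalation; criterion 2 is a symptom-score
increase of at least 10 points over the baseline-week daily mean on at
least 2 illness days *plus* at least one objective change — albuterol at
least 4 puffs/day over the baseline mean for at least 2 days, FEV1
decline of at least 10% at an illness visit versus baseline, or PEF at or
below 80% of the *best* baseline-week PEF for at least 2 days. Twice-daily
diary entries are aggregated to daily values before thresholding (this
makes the "for ≥ 2 days" counts well defined); daily totals, not
per-entry scores, are compared against baseline + 10. All thresholds are
configurable through `exacerbationCriteria()`.

Supporting tests use midranks throughout: Friedman's tie-corrected
chi-squared across the three visits (the fully tied table is defined as
statistic 0, p = 1), Mann-Whitney U with exact enumeration of all
assignments when both samples have at most 8 observations and a
tie-corrected normal approximation with continuity correction otherwise,
and Spearman correlation with exact permutation p for n ≤ 7 and a t
approximation otherwise. qPCR abundances are normalized to the
arithmetic mean Ct of the two housekeeping genes (GAPDH and PPIA in the
assays this models), i.e. the geometric mean of their abundances:
$2^{-(Ct_\mathrm{target} - \bar{Ct}_\mathrm{ref})}$.

# The synthetic cohort generator

`simulateCohort()` is a first-class module, not a test fixture. Each
observation is

$$y_{g,s,t} = \mu_g + \delta_{g,\mathrm{cell}(s,t)} + b_{g,s} +
\varepsilon_{g,s,t}$$

with per-gene baseline $\mu_g \sim U(4, 14)$ log2 units (the typical
array intensity range), planted cell offsets $\delta$, subject random
intercepts $b \sim N(0, \frac{\rho}{1-\rho}\sigma^2)$ and noise
$\varepsilon \sim N(0, \sigma^2)$ — which induces exactly the
equicorrelation $\rho$ that the GLS stage assumes. Defaults are the
validation conditions used throughout: 4 groups of 8 subjects by 3
visits, 5,000 genes, noise $\sigma = 0.5$ log2 units, $\rho = 0.3$, and
three planted sets: 60 core-D2 genes (+1.5 log2 at D2, all groups),
70 shared-D6 genes (+1.5 at D6 in the three non-exacerbation groups) and
90 distinct-D6 genes (−1.5 at D6, exacerbation group only). Missing
visits drop whole samples. All randomness keys off a single seed with
deterministic per-stage sub-seeds, so identical configurations are
bit-identical and stages can be regenerated independently.

`simulateClinical()` builds diaries and spirometry such that subjects
flagged as exacerbating satisfy criterion 2 by construction (+15 symptom
points on three days, +6 puffs on two days) and all other subjects stay
strictly inside every threshold; this gives the adjudicator an exact
ground truth.

What the generator does *not* emulate: probe-level array artefacts
(control probes, background, flags), heteroscedastic mean-variance
trends, virus genotypes, or subject-level covariates (age, sex,
medication) as expression confounders. Passing tests on this generator
therefore demonstrate correctness of the estimation and classification
machinery under the model's own assumptions, not robustness to real
microarray artefacts.

# Numerical choices and problem sizes

* Profile size $N = 100$ and $\alpha = 0.05$ are the study's stated
  choices, kept configurable via `pipelineConfig()`.
* Probes are treated as gene-level units (no probe-to-gene collapsing).
* Exact-test enumeration limits (Mann-Whitney at 8 per side, Spearman at
  n = 7) keep exact computation deterministic and fast on the sample
  sizes this design produces.
* The validation suite uses cohorts of 300–5,000 genes and 4–8 subjects
  per group, and 200 replicate null cohorts for the family-wise error
  estimate; these sizes give stable estimates while keeping the full
  suite around half a minute.
* Degenerate inputs are defined rather than undefined wherever a
  downstream table must remain writable: constant genes scale to 0.5
  (flagged), identical paired scores test as t = 0, and the fully tied
  Friedman table is chi-squared 0.

# Known limitations

The group-pooled time contrasts are, by design, insensitive to effects
confined to a single group: an exacerbation-only change of $\Delta$
enters each contrast as $\Delta/4$, so at these sample sizes
single-group signals need to be roughly three times larger than
all-group signals to survive Holm selection into the ARI set. Relatedly,
when the selected ARI universe is not much larger than the profile size
$N$, the per-group profiles overlap heavily by construction and the
core/shared/distinct geometry loses specificity — meaningful distinct
signatures require a universe comfortably larger than $N$. Both effects
are quantified honestly by the package's validation suite on the default
synthetic conditions (where single-group planted genes are largely not
recovered), and both reflect properties of the published design that the
package reproduces rather than repairs.

# Reproducing the study's descriptive numbers

`referenceCohortCounts()` embeds the reference cohort's per-group
participant counts (9 / 7 / 23 / 11 of 50) and `groupPercentages()`
recomputes their percentage composition (18 / 14 / 46 / 22 / 100). The
`scripts/acceptance.R` entry point recomputes every headline quantity of
the package — recovery rates, error calibration, consensus-correlation
recovery, adjudicator agreement, and the hand-checkable worked-example
statistics — from scratch on freshly simulated cohorts.
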