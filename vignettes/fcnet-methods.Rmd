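---
title: "Methods: weighted small-world analysis of functional connectomes"
author: "fcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted small-world analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

# The analysis in one paragraph

fcnet implements a complete group-comparison pipeline for resting-state
functional connectomes at the region-of-interest (ROI) level. Each
subject contributes a T x N matrix of ROI-averaged BOLD-like signals.
After cleaning (linear detrend, 0.01–0.08 Hz zero-phase band-pass,
nuisance regression of the Friston-24 motion expansion), the N x N
Pearson correlation matrix is thresholded by Bonferroni-corrected edge
significance with negative correlations excluded, yielding a
positive-weight undirected network per subject. Networks are summarized
by weighted small-world efficiency — global, local, and nodal — using
reciprocal-weight edge lengths, normalized against degree-preserving
random rewirings. Group differences are inferred nonparametrically:
permutation tests for global metrics, Benjamini–Hochberg FDR across
nodes, and the network-based statistic (NBS) for edge components.
Finally, metric–behavior associations are assessed by partial
correlation controlling age, sex, and education.

# The model and its assumptions

**Functional distance.** An edge weight is the retained correlation
$w_{ij} \in (0, 1]$, and its length is $1 / w_{ij}$: strongly
correlated regions are functionally close. Shortest paths $d_{ij}$
minimize summed lengths (Dijkstra). Efficiency metrics are

$$E_{glob}(G) = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{d_{ij}}, \qquad
  e_i = \frac{1}{N-1} \sum_{j \ne i} \frac{1}{d_{ij}}, \qquad
  E_{loc}(G) = \frac{1}{N} \sum_i E_{glob}(G_i),$$

where $G_i$ is the subgraph induced on the neighbors of node $i$. The
identity $E_{glob} = \mathrm{mean}_i(e_i)$ is exact and is asserted to
1e-12 in the test suite.

**Unreachable pairs.** Disconnected pairs contribute $1/\infty = 0$
rather than being dropped. This matters in practice: Bonferroni
thresholding occasionally isolates a node, and the efficiency framework
handles such graphs without special-casing — one of its advantages over
characteristic-path-length summaries.

**Neighbor subgraphs in $E_{loc}$.** $G_i$ keeps the original weights
between the neighbors of $i$ and excludes $i$ itself; weights are not
rescaled by the weights to node $i$. This is the plainest reading of
the Latora–Marchiori formulation and the one implemented here. A
subgraph with fewer than two nodes contributes zero.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass | 0.01–0.08 | Hz | conventional resting-state fluctuation band |
| filter design | Butterworth order 4, forward–backward | — | zero phase: filtering must not shift correlations in time |
| Bonferroni alpha | 0.05 | — | family-wise level over the N(N-1)/2 unique connections |
| head radius (FD) | 50 | mm | Power convention for converting rotations to arc length |
| motion exclusion | 2 mm / 2° | — | standard rigid-body quality-control rule |
| n_random | 100 | networks | normalization denominator; SE of the mean scales as $1/\sqrt{n}$ |
| swap_factor | 20 | swaps/edge | enough double-edge swaps for topology decorrelation on graphs of this scale |
| n_perm | 10,000 | relabelings | permutation resolution ~1e-4; reduced sizes used in tests (below) |
| primary alpha (NBS) | 0.05 | — | edge-level one-sided threshold forming components |
| positivity rule | > 85% | subjects | an edge enters NBS only if its raw correlation is positive in more than 85% of all subjects |
| FDR q | 0.05 | — | nodal comparison correction level |

# Numerical and procedural choices

**Filter.** No specific filter design is canonical for this band; we
use a fourth-order Butterworth applied forward and backward
(`signal::filtfilt`), whose squared-magnitude response meets a ≥ 0.9
pass-band and ≤ 0.1 stop-band amplitude ratio on 230-frame sinusoids.
Columns are demeaned first so DC maps to exactly zero.

**Framewise displacement.** FD is the Power convention: the sum of
absolute backward differences of the six parameters, rotations scaled
by a 50 mm head radius, FD(1) = 0. The convention and radius are
arguments, not constants.

**Cleaning order** is fixed — detrend, then filter, then nuisance
regression — and the operations are linear, so the pipeline applied to
a sum of signals equals the sum of pipelines (property-tested).

**Edge p-values** come from the t transform
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom; this treats
frames as independent samples. Band-pass filtering reduces the
effective degrees of freedom, so these p-values are anti-conservative
in absolute terms; since they are used only as a ranking device for a
fixed Bonferroni cut (the convention this pipeline follows), this affects the
operating density of the graphs, not the validity of the group
inference, which is permutation-based throughout.

**Random-network weights.** The rewiring null preserves nodes, edges,
and the exact degree sequence by double-edge swaps (a swap creating a
self-loop or duplicate edge is rejected; a complete graph is returned
unchanged with a warning). The original weight multiset is then
reassigned to the rewired edges in a seeded random permutation. The
alternative — carrying weights with their edges through swaps — is
statistically indistinguishable for the ratio statistics used here; we
prefer the shuffle because it also randomizes any weight–degree
coupling, making the null strictly weaker.

**Permutation p-values** use the add-one (never-zero) estimator
$(1 + \#\{null \ge obs\}) / (1 + n_{perm})$; the 95th-percentile
critical-value rule is computed alongside, and the two decisions can
disagree only within $1/n_{perm}$ of the 0.05 level. When the total
number of distinct relabelings is at most `nPerm`, the engine
enumerates all of them and the p-value is exact. Ties are counted with
a relative tolerance of 1e-10 so that relabelings reproducing the
observed difference are not lost to floating-point summation order.

**NBS null counting** uses "at least as large" ($\ge M$), the
conservative standard convention; strict exceedance is available via
`strictNull = TRUE`. The positivity rule is evaluated on raw
(pre-threshold) correlation signs across all subjects pooled, strict
inequality. The edge-level test is a one-sided pooled-variance t per
direction, with both directions (A>B, B>A) run separately by the
pipeline.

**Small-world rule.** A network is classified small-world when its
normalized global efficiency is within `globTol = 0.1` of 1 and its
normalized local efficiency exceeds $1 + locTol$ with `locTol = 0.05`.
The margin exists because the strict textbook rule (`> 1`) has no
discriminating power against the rewiring null's own sampling
fluctuation: a random graph is statistically its own null, its
normalized local efficiency straddles 1, and a strict rule would label
about half of all random graphs small-world. `locTol = 0` restores the
strict reading. Empirically (test suite), shortcut-augmented ring
lattices score far above the margin (ratios ≈ 4–5) while dense random
graphs stay within ±0.02 of 1.

**Demographic tests** are pooled-variance Student t-tests (not Welch)
and Pearson chi-square without continuity correction — the forms under
which typical printed cohort-table p-values (e.g. 0.699, 0.054, 0.872
in the worked examples) reproduce to their stated precision.

# The synthetic cohort generator

The generator emulates the statistical skeleton the analysis assumes,
not BOLD physiology:

* **Community structure.** The population covariance is block-constant:
  `withinBlockCov` inside each block (a stand-in for a functional
  system, e.g. a "DMN-like" community), `betweenBlockCov` elsewhere,
  diagonal $1 + \sigma^2_{noise}$. Positive-definiteness is validated;
  a non-PD assembly is repaired by nearest-PD projection with the
  maximal entry change logged and a hard error beyond 0.05.
* **Group effect.** Group A adds `effectDelta` symmetrically on a
  designated edge set, so the expected group difference in sample
  correlation is nonzero only there (property-tested at large T).
* **Temporal structure.** Innovations are multivariate normal, passed
  through a lag-1 autoregression (default coefficient 0.3). AR(1) plus
  Gaussianity is a modeling convention chosen for tractability — real
  BOLD has richer spectra — but it preserves the cross-sectional
  correlation structure the pipeline estimates.
* **Subject heterogeneity.** Each subject receives a connectivity
  strength $g_s \in (0,1)$ (logit-normal, median 0.75, logit-scale SD
  `subjectStrengthSd = 0.5`) and covariance
  $\Sigma_s = g_s \Sigma + (1-g_s)\,\mathrm{diag}(\Sigma)$ — always
  positive-definite, variances untouched. This models the global
  connectivity differences between individuals that drive
  brain–behavior coupling: the `coupled` behavioral score is
  `behaviorCoupling` times the subject's mean generating covariance on
  the effect edges plus Gaussian noise, so recovery of the coupling by
  partial correlation is testable within a group.
* **Demographics and scores.** Age, sex, and education are drawn from
  identical distributions in both groups (a matched design, carrying no
  built-in effect); the named questionnaire scores are drawn at
  patient-like versus control-like levels, with ESS and disease
  duration missing for the control-like group as is typical of
  clinical reporting.
* **Motion.** Six-parameter Gaussian random walks (translations:
  per-step SD `amplitude` mm; rotations: `amplitude`/50 rad), enough to
  exercise FD summaries and the exclusion rule.

Defaults mirror a two-group resting-state study: 36 + 38 subjects, 246
ROIs in six near-equal blocks, 230 retained volumes at TR = 2 s. The
generator emits post-discard series directly (dummy-scan removal is an
image-level step outside this package's boundary).

What the generator does **not** emulate: voxel-level imaging,
physiological (cardiac/respiratory) noise, spatial autocorrelation,
scanner drift beyond a linear trend, non-Gaussian BOLD amplitude
distributions, or site/batch effects. Passing tests therefore
demonstrate correctness of the estimators and calibration of the
inference under the assumed data model — not robustness to everything
real fMRI can do.

# Test problem sizes and calibration fixtures

The test suite runs the statistical machinery at reduced,
well-conditioned sizes chosen so the whole suite completes in a few
minutes on one core while keeping every Monte-Carlo check adequately
powered:

* **Permutation calibration:** 1,000 null simulations of 8 + 8 cohorts
  at 1,000 permutations; expected type-I band 0.035–0.065.
* **NBS calibration:** 1,000 null cohorts of 20 ROIs (two independent
  10-ROI systems, within-system covariance 0.3, subject-strength SD
  0.1), 8 + 8 subjects, 230 volumes, 1,000 permutations. Two
  independent systems of 10 give a connected-component size
  distribution with fine granularity near its 95th percentile, which is
  what a rate-level check of an integer-valued statistic needs;
  observed family-wise error 0.046.
* **NBS recovery:** 50 cohorts with a 6-edge clique planted in one of
  four independent 5-ROI systems (`effectDelta = 0.4`, subject-strength
  SD 0.1). Small, mutually independent systems keep spurious
  suprathreshold edges from chaining across the graph, so the planted
  component is recovered cleanly (Jaccard ≥ 0.6 with corrected
  p < 0.05 in 100% of cohorts at these settings). With larger, richer
  systems the same planted effect is still detected but accretes
  incidental edges — the familiar specificity cost of
  component-forming inference, visible here by construction.
* **Small-world detection:** 60-node ring lattices (degree 4) with 60
  shortcuts versus density-0.3 random graphs, 20 seeds each, 20
  rewires per normalization.

# Known limitations

* Efficiency normalization at full scale (246 ROIs, 100 rewires,
  74 subjects) is compute-intensive in pure R; the pipeline is
  routinely run at reduced ROI counts for validation, and the per-stage
  structure makes it straightforward to parallelize over subjects
  externally if needed.
* Edge-level p-values ignore temporal autocorrelation (see above).
* The NBS implementation supports component size (link count) as the
  cluster statistic; intensity-weighted variants are out of scope.
* Negative correlations are excluded by design, following the source
  methodology; no signed-network analysis is attempted.
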