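---
title: "Measuring robustness of longitudinal brain networks with Ollivier-Ricci curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring robustness of longitudinal brain networks with Ollivier-Ricci curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccinet)
```

## The model

A structural connectome is an undirected, positively weighted graph
$G = (V, E)$: nodes are parcellated gray-matter regions, and the weight
$w_{xy} \ge 0$ of an edge is the volume of tractography streamlines joining
regions $x$ and $y$, normalized by whole-brain white-matter volume (so
weights are dimensionless and comparable across subjects). `riccinet`
represents this as a `brain_network`: a validated symmetric non-negative
matrix plus a node table with region names and hemisphere labels
(`left`/`right`, with the brainstem labeled `none`).

On the vertex set we use the graph metric $d(x, y)$, by default the **hop
metric** — the number of edges on the shortest path, each positive-weight
edge counting as length one. Any intrinsic metric is admissible, and an
inverse-weight metric (edge length $1/w_{xy}$, so strong connections are
metrically short) is available via `metric_kind = "weighted"`; the hop
metric is the default because it makes the curvature's scale properties
transparent (see below) and keeps $d(x, y) = 1$ for adjacent nodes.

Each non-isolated node $x$ carries the one-step random-walk measure
$$\mu_x(y) = \frac{w_{xy}}{d_x}, \qquad d_x = \sum_z w_{xz},$$
over its neighbors. The walk is **non-lazy**: no mass remains at $x$. Much
published curvature software defaults to a lazy walk with idleness
$\alpha = 1/2$; the two conventions give different numbers, so the choice
is stated explicitly here and fixed throughout.

The **Ollivier-Ricci curvature** of an edge is
$$k(x, y) = 1 - \frac{W_1(\mu_x, \mu_y)}{d(x, y)},$$
where $W_1$ is the Wasserstein-1 (earth mover's) distance between the two
walk measures under the ground metric $d$. When the neighborhoods of $x$
and $y$ overlap — shared neighbors, triangles, feedback — little mass needs
to travel far, $W_1 < d(x,y)$, and the curvature is positive; a bare bridge
between separate clusters forces mass across the bridge and the curvature
is negative. Curvature is bounded above by 1 always, and below by $-2$ for
adjacent nodes under the hop metric (every relevant ground distance is at
most 3). The **scalar curvature** of a node contracts the edge values:
$$\hat S(x) = \sum_y \mu_x(y)\, k(x, y),$$
a convex combination of the incident edge curvatures. Curvature is used
throughout as a proxy for robustness — the capacity of a connection or
region to withstand perturbation — via the positive
curvature–entropy–robustness association.

### Exact values worth remembering

* a lone edge: $k = 0$ (each measure is a point mass on the other endpoint);
* interior edges of a unit-weight path: $k = 0$;
* the complete graph $K_n$ with unit weights: $k = (n-2)/(n-1)$ on every
  edge;
* pendant edges have $k = 0$ at *any* weights under the hop metric — which
  matters for the longitudinal ratio below.

These closed forms double as test oracles, each confirmed independently by
a brute-force transport solver before being frozen into the test suite.

## Computing $W_1$

$W_1(\mu_x, \mu_y)$ is solved exactly as a balanced transportation linear
program restricted to the two neighbor supports, with ground distances
taken from the full graph. The production solver is a compiled
transportation simplex (northwest-corner start, u–v pivoting on the basis
tree, most-negative-reduced-cost entering rule, optimality tolerance
$10^{-9}$); a plain-R implementation of the identical algorithm ships in
the package (`engine = "reference"`) and the test suite cross-checks both
against two independent implementations: a general-purpose LP solver and,
for supports of up to four atoms, exhaustive enumeration of the vertices of
the transportation polytope. Only the optimal *cost* is contractually
unique — degenerate problems admit many optimal plans — so all downstream
code and all tests depend on the cost alone.

Disconnected graphs are handled per component: the supports of two adjacent
nodes lie within distance 1 of the edge, so an edge can never straddle
components, and only fully isolated nodes are excluded (their walk measure
is undefined).

Two numerical conventions: self-loops are dropped at load with a warning
(the walk measure is defined over neighbors), and matrices asymmetric
beyond $10^{-8}$ are rejected rather than silently symmetrized —
tractography output is symmetric by construction, so larger asymmetry
signals a corrupted file. Asymmetry within tolerance is averaged away.

Under the hop metric, multiplying all weights by $c > 0$ changes neither
$\mu_x$ nor the metric, so curvature is scale-invariant — the whole-brain
volume normalization affects nothing downstream, and `normalize_edge_weights()`
is provided for completeness and for inputs that arrive unnormalized.

## The longitudinal pipeline

`run_analysis()` takes a cohort (a tibble with baseline and follow-up
networks and three behavioral change scores per subject) and:

1. removes cross-hemisphere edges (configurable; edges touching the
   brainstem are kept by default, since the hemisphere-removal rule speaks
   only of left–right pairs — the brainstem flag is exposed rather than
   asserted);
2. computes edge and scalar curvature at both timepoints;
3. forms the per-unit change **ratio** (follow-up over baseline). A ratio
   rather than a difference is used because curvature is unitless; the
   ratio is undefined when the baseline magnitude is below
   $\varepsilon = 10^{-12}$ or the unit is absent at either timepoint, and
   such units are flagged, not silently dropped. Ratios may legitimately be
   negative (curvature can cross zero) and are retained;
4. correlates each retained unit's ratios with each behavioral score by
   Spearman rank correlation (average ranks for ties; two-sided p from the
   t approximation on $n - 2$ degrees of freedom, adequate at cohort sizes
   around 19 — an exact-permutation alternative matters only below
   $n \approx 10$);
5. flags a unit **selected** when $p < 0.05$ on at least two of the three
   measures, and applies Benjamini–Hochberg correction at
   $\alpha = 0.05$.

The three behavioral scores follow the clinical conventions: change in the
Vineland socialization subscale and in expressive vocabulary are follow-up
minus baseline (higher = better), while the clinical global
impression–improvement rating is used directly and is inverted (lower =
more improvement). Improvement-coupled connectivity change therefore shows
positive correlations with the first two measures and negative with the
third — the sign pattern the pipeline checks for.

**BH families.** Correction is applied within each unit-type × measure
family: all edges for one measure form one family, separately from nodes.
Pooling edges with nodes would mix two statistics with very different unit
counts and dependence structure; pooling measures would correct a
deliberately redundant two-of-three rule. Both choices are configurable in
principle, but the per-family default is what the results tables report. A
selected unit `survives_fdr` when at least the same number of measures
that drove selection have $q < \alpha$, paralleling the selection rule at
the corrected level.

**Unit inclusion.** A unit enters the correlation stage only when its
ratio is defined for all subjects by default (`min_valid` relaxes this,
with an absolute floor of four subjects). With fewer valid subjects the
ranks, and thus the selection flags, would not be comparable across units.

## The synthetic-cohort generator

Subject-level imaging and clinical data of the kind this package targets
are rarely shareable, so the generator is the package's test bed: it emulates a
19-subject, 83-region cohort (41 regions per hemisphere plus brainstem)
with a shared intra-hemisphere topology (regions come from a common atlas),
log-normal weights drawn independently per subject, within-subject weight
changes, and behavioral scores coupled to a per-subject latent improvement
$L \sim N(0,1)$.

Key choices, and why:

* **Weights** are log-normal (`meanlog = -6`, `sdlog = 0.6`): strictly
  positive and right-skewed like normalized streamline volumes. The spread
  matters: with `sdlog` near 1 the baseline curvature of a given edge
  straddles zero across subjects, making follow-up/baseline ratios
  incomparable between subjects and drowning any planted signal — the
  generator would then fail to produce the very statistical structure the
  analysis assumes (the study's selected pathways correlate with behavior
  at $|r| \approx 0.5$–$0.75$). `sdlog = 0.6` yields stable positive
  curvature for triangle-rich pathways while keeping realistic
  heterogeneity.
* **Density** of intra-hemisphere connections defaults to 0.45, in the
  range of deterministic-tractography connectomes at this parcellation;
  each hemisphere is resampled until connected, and the brainstem attaches
  to a few nodes of each hemisphere.
* **Planted effects act on weights, not on curvature.** For each planted
  pathway — an intra-hemisphere edge chosen among the most triangle-rich
  (most shared neighbors; a pendant edge would have identically zero
  curvature and no defined ratio) — the flanking edges to every shared
  neighbor are multiplied by $e^{\text{effect\_size} \cdot L}$ at
  follow-up. Strengthening a pathway's triangle support concentrates both
  endpoint walk measures on common neighbors, monotonically *raising* the
  pathway's curvature. This is the feedback-through-triangles mechanism by
  which denser local connectivity confers robustness, and it reproduces
  the clinically observed direction (improvement associated with increased
  robustness). Multiplying the planted edge's *own* weight instead — the
  naive choice — predominantly *lowers* its curvature and responds
  non-monotonically at large effects, because both walk measures then
  concentrate on the opposite endpoints; the flank mechanism was adopted
  after that failure mode was characterized.
* **Test-retest noise**: every edge weight at follow-up is additionally
  multiplied by log-normal noise (`weight_noise_sd = 0.05`), emulating
  scan-rescan variability.
* **Behavioral scores** are anchored to the observed cohort summary
  statistics (change in socialization $3.37 \pm 6.71$, change in
  expressive vocabulary $4.95 \pm 6.34$, improvement rating
  $2.79 \pm 1.82$): each score is
  $m + s\,(\pm L + \text{noise\_sd}\cdot e)/\sqrt{1 + \text{noise\_sd}^2}$,
  giving exactly those moments in expectation while `noise_sd` sets the
  noise-to-signal ratio of the coupling. The improvement rating takes the
  minus sign. The rating is kept continuous rather than rounded to its
  ordinal 1–7 scale; rounding would only add ties, which the
  average-rank Spearman handles, at the cost of a clean coupling.
* The entire cohort is a pure function of the configuration, including its
  seed.

What the generator does **not** emulate: spatial structure and distance-
dependent connection probability, hub/rich-club organization,
subject-level topology differences, sedation or scanner effects, and
ordinal measurement of the rating scales. Passing recovery tests therefore
demonstrate that the pipeline detects improvement-coupled weight
reorganization through curvature in networks of realistic size, sparsity
and weight scale — not that it would do so under every property of real
DTI data.

## What recovery can and cannot show

With zero behavioral noise and a large effect, every planted pathway is
recovered (sensitivity 1). But curvature is deliberately **non-local**:
the flanking edges whose weights change, and the scalar curvature of the
nodes they touch, respond to the same latent improvement, and with
noiseless behavioral coupling any systematically responding unit is
selected. "False positives" counted as *selected units that are not
planted edges* are therefore structurally nonzero in the noiseless strong
regime — they are collateral detections of a genuinely perturbed
neighborhood, not statistical errors. The corresponding expectation is
kept in the acceptance suite as a documented, intentionally failing check
rather than being redefined away. Under the null (no effect), the
per-measure type-I rate at $p < 0.05$ is calibrated (0.03–0.07 across 500
replicates) and the two-of-three selection rate stays below 3%.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run: the oracle comparison on 50
random graphs of up to 8 nodes; structural invariants on 50 random graphs
of up to 10 nodes; the null calibration on a 41-region effectless cohort
(200 units × 500 behavior replicates); the strong-regime recovery at the
full study scale (19 subjects, 83 regions, `effect_size = 1.5`,
`noise_sd = 0`); and the moderate regime (`effect_size = 0.5`,
`noise_sd = 0.5`) on 21-region cohorts across dozens of seeds against a
matched effect-free null. The 21-region moderate cohorts trade network
size for seed coverage; the strong-regime run keeps the full 83-region
geometry.

## Known limitations

* The hop-metric default follows the stated graph metric; whether a
  weighted ground metric is preferable for connectomes is an open
  modeling question (both are implemented).
* No thresholding of weak edges is applied by default; very small weights
  legitimately influence walk measures.
* The ratio change measure is intrinsically unstable near zero baseline
  curvature; affected units are excluded per subject, which can drop a
  unit entirely under the all-subjects inclusion default.
* The pipeline tests marginal associations per unit; no longitudinal
  mixed models, covariate adjustment, or spatial dependence modeling.
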