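---
title: "Methods: from prey models to trafficking-route networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from prey models to trafficking-route networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildroute)
```

`wildroute` implements a three-stage decision-support chain for locating
probable trafficking routes of live animals: presence-only prey
distribution models, a rule-based habitat suitability index (HSI) for the
predator, and a multimodal routing model over a road-and-sea transport
graph. This vignette records the models, their assumptions, the tunable
parameters, and the numerical and design decisions a maintainer needs.

## Stage 1: presence-only prey models

### Model

For each prey species we fit a maximum-entropy density model over the
landscape. With features $f(x)$ (linear and quadratic transforms of each
covariate, standardized to mean 0, sd 1 over the background sample) the
relative suitability of a cell is $s(x) = \exp(w \cdot f(x) - \log Z)$,
normalized so the background mean of $s$ is 1. Weights maximize the
penalized log-likelihood

$$\frac{1}{n_p}\sum_{i \in \text{presences}} w \cdot f(x_i)
  \;-\; \log \frac{1}{n_b}\sum_{j \in \text{background}} e^{w \cdot f(x_j)}
  \;-\; \beta \sum_j \lambda_j |w_j|,$$

with per-feature penalties $\lambda_j = \mathrm{sd}_j(F_p)/\sqrt{n_p}$
(features more variable among presences are penalized more; the
$1/\sqrt{n_p}$ factor lets penalties fade with sample size). $\beta$ is
the familiar regularization multiplier, default 1.

Assumptions worth stating: presences are a biased sample of a density
proportional to habitat quality; background points characterize available
environment; feature classes are limited to linear + quadratic terms. We
deliberately omit hinge, product and threshold features — the acceptance
surface of this package (coefficient-sign recovery, ranking performance,
threshold binarization) does not require them, and the smaller feature
space keeps fits convex, fast and interpretable.

### Survey bias and the target-group background

Opportunistic occurrence data oversample accessible places. Because the
same accessibility gradient affects every surveyed species, using the
pooled occurrence locations of *all other species* as background (the
target-group background, `target_group_background()`) puts the same bias
on both sides of the presence/background contrast, where it cancels. The
cost is equally real: signal *shared* by the whole species group cancels
too, so AUCs against a target-group background run lower than against
uniform background. That is expected behavior, not a defect.

### Tuning, evaluation, thresholding

* Covariate pruning: one of each pair with |r| > 0.7 (Spearman by
  default) is dropped; from a violating pair we drop the layer with the
  larger mean absolute correlation to everything else (ties by name), a
  deterministic rule that keeps the more independent layer.
* Train/test split: 70/30 random partition of presences under a fixed
  seed; the background is shared. The split fraction is a free parameter
  (`split = 0.3`).
* Overfitting control: while the train−test AUC gap exceeds
  `overfit_gap`, $\beta$ doubles (at most 5 doublings). The default gap
  is 0.05. A printed gap criterion of 0.5 exists in the methodology
  literature this follows, but an AUC gap of 0.5 is nearly unattainable
  (it requires a near-perfect train fit and a test fit near chance), so
  0.05 is the default and any other value can be supplied.
* Binarization: the maxSSS threshold — the observed score maximizing
  (sensitivity + specificity)/2, ties resolved to the smallest threshold.
  Scores within 1e-12 of the maximum count as tied, which makes the rule
  robust to floating-point noise in the tied sums.
* The logistic display transform maps raw suitability through
  $cs/(1+cs)$ with $c$ solved so the background mean equals a prevalence
  constant (default 0.5, configurable). Everything downstream of maxSSS
  is invariant to this monotone transform; it exists for map legibility.

### Optimizer

Proximal gradient (FISTA) with backtracking on the smooth part and
soft-thresholding for the L1 term, initialized at zero weights, stopping
when the generalized-gradient sup-norm falls below 1e-6 (warning after
1e4 iterations). Deterministic by construction — no random restarts.

## Stage 2: HSI and core habitat

The HSI keeps the prey-richness value (0–7) wherever two masks pass and
is 0 elsewhere: human modification must be **below** 0.25 and crop cover
**below** 0.10; boundary equality resolves toward *unsuitable*. Nodata in
any input propagates.

Core habitat is extracted where the index exceeds 4 (strictly: classes
5–7 qualify). Cell centers of qualifying cells feed an unweighted
Gaussian KDE (a cell at 7 counts once, like a cell at 5 — the procedure
selects by exceedance, and weighting is an open choice we resolved to
"unweighted" for simplicity and because the isopleth is insensitive to it
on clustered inputs). Bandwidth defaults to Scott's rule
($h_d = \mathrm{sd}_d \, n^{-1/6}$ per axis), user-overridable. The 90%
isopleth uses the standard volume-contour method: evaluate the KDE on the
raster lattice, sort cell densities descending, accumulate cell mass
until the target fraction is reached, and vectorize the selected cells
into polygons (boundary edges are chained with the region interior on the
left; clockwise rings become holes). Degenerate inputs: zero qualifying
cells return an empty `core_habitat` with a warning.

## Stage 3: the trafficking network

### Graph and weights

A directed graph: nodes carry planar coordinates (km); edges carry
length (km), speed (km/h), mode (road class or `water`) and a one-way
flag; two-way edges are stored as reciprocal directed edges. Travel time
is length ÷ speed — the dimensionally correct quotient (a *product* of
length and speed is not a time). Water crossings enter at dhow speed,
20 knots × 1.852 = 37.04 km/h, bidirectional.

Class-default speeds (km/h) when an input omits them: motorway 100,
trunk 80, primary 70, secondary 60, tertiary 40, residential 30, water
37.04.

### Simplification

Interstitial nodes — degree-2 pass-throughs on a uniform-mode chain —
are removed and their edges merged: merged length is the sum of lengths,
merged time the sum of times, merged speed length/time (the harmonic
speed combination). One-way chains merge only when direction is
consistent along the chain. This preserves every shortest distance and
time between retained nodes exactly (tested to 1e-6). Optional node
consolidation (clusters within a radius collapse to their centroid)
intentionally changes geometry and is off by default; the preservation
guarantee applies only to the merge step.

### Routing

* `shortest_path()`: Dijkstra with deterministic tie-breaking — among
  equal tentative costs the smallest node id settles first, and
  relaxation updates only on strict improvement. Unreachable
  destinations are reported (`NULL` / counted in summaries), never
  silently dropped.
* `k_shortest_routes()`: Yen's loopless k-shortest algorithm with a
  Dijkstra subroutine; candidate ties break on (cost, node sequence).
  Yen's is the standard choice for "N optimal routes" when loops are
  meaningless, and is directly checkable against brute-force path
  enumeration.
* `isochrone()`: single-source Dijkstra on the edge-reversed graph gives
  times *to* the anchor; nodes bin into `floor(time / 8 h)` travel-day
  classes by default.
* Origins: ~100 uniform points per habitat polygon (rejection sampling),
  snapped to the nearest node (ties to the smaller id) and deduplicated
  before routing; collapse counts are retained so multiplicity weighting
  remains possible. Route transit counts per node rank bottlenecks.

## The synthetic world

The generator builds the study conditions every test runs under:

* a 64 × 64 lattice of 1-km cells (tests use 16–48 per side where the
  property under test allows it); seven covariate layers — two axis
  gradients and a sinusoidal elevation-like surface (closed-form trend +
  iid noise, sd 0.1), two land-cover proportions, human modification and
  crop cover, all clamped to [0, 1];
* seven prey species, 150 presences each by default (500 in the
  recovery experiments), sampled per cell with probability
  ∝ sigmoid(β·z) under a shared logistic response: intercept −4 (keeping
  prevalence near 0.2, a restricted-range species), −2 on the west–east
  gradient and −1.5 on human modification, plus two idiosyncratic ±2
  terms rotating through the remaining layers — species share a
  favorable region (the low-gradient landmass) yet stay distinguishable
  against a target-group background;
* a shared survey-bias surface: sampling probability is multiplied by
  `exp(bias_strength × accessibility)`, accessibility a smooth gradient
  from a "survey town" corner, identical for all species so the
  target-group background can cancel it;
* two road lattices ("landmasses") separated by a strait, with random
  road classes, a 15% one-way fraction, explicit degree-2 chains to
  exercise simplification, and two dhow-speed water crossings; habitat
  polygons sit over the highest true-suitability cells of the west
  landmass, and 34 destination points jitter around east-landmass nodes.

What it does **not** emulate: spatial autocorrelation in the noise
fields, real land-cover class structure, detection/effort covariates,
road geometry (edges are straight segments), seasonal sea conditions, or
any behavioral model of traffickers. Passing tests therefore show the
*machinery* is correct and the inference is recoverable under known
conditions — not that any specific real landscape obeys the model.

## Reproducibility

Every generator and every pipeline run derives all randomness from one
integer seed (generators use fixed offsets of it so streams do not
alias), and global RNG state is restored after each call. File writers
format numbers deterministically, so identical config + seed yields
byte-identical artifacts; `run_pipeline()` writes a manifest with MD5
checksums per artifact. Stages communicate only via serialized files,
which makes each stage's contract testable in isolation and partial
reruns possible.

## Known limitations

* Linear + quadratic features only; no hinge features, clamping or
  extrapolation flags from the desktop Maxent lineage.
* Single train/test split, no cross-validation folds.
* Planar coordinates in km; there is no projection engine, and inputs
  must arrive co-registered (readers enforce this and refuse mismatches).
* No traffic, congestion, turn restrictions, or stochastic route choice;
  routes are ranked and visualized, not behaviorally simulated.
* KDE bandwidth defaults to Scott's rule; strongly multimodal source
  patterns may warrant a user-supplied bandwidth.
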