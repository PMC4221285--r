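---
title: "Modelling bird ranges with maxent and attributing change to climate versus land use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bird ranges with maxent and attributing change to climate versus land use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Species distribution models (SDMs) relate where a species has been observed
to environmental conditions, and are routinely projected onto future climate
to anticipate range shifts.  Land-use/land-cover (LULC) change is at least as
consequential for habitat as climate change, but high-resolution LULC
projections are rarely used.  This package implements an end-to-end,
presence-only workflow that fits a maximum-entropy (maxent) model to
occurrence records with climate, LULC and topographic covariates, and then
disentangles the contributions of projected climate versus projected LULC
change by re-projecting the fitted model onto hybrid covariate stacks in
which only one family of covariates is allowed to change.

Because real continental inputs (citizen-science occurrence archives,
downscaled circulation-model ensembles, LULC projections) are large and
access-restricted, the package ships a synthetic-world generator with
virtual species whose true suitability is known.  Every stage of the
pipeline can therefore be validated against ground truth, and the package's
tests are exactly such validations.

## The maxent model

Let \(x\) index grid cells, \(f_j(x) \in [0,1]\) a set of features built from
min-max-scaled covariates, and \(\lambda_j\) their weights.  The model is the
Gibbs density over the background sample,

\[
q_\lambda(x) = \frac{e^{\eta(x)}}{Z_\lambda}, \qquad
\eta(x) = \sum_j \lambda_j f_j(x), \qquad
Z_\lambda = \sum_{x \in \text{background}} e^{\eta(x)},
\]

fitted by minimizing the L1-penalized objective

\[
J(\lambda) = -\frac1m \sum_{i=1}^{m} \eta(x_i) + \log Z_\lambda
           + \sum_j \beta_j |\lambda_j|,
\]

the negative presence log-likelihood plus penalty.  This is the convex dual
of maximum-entropy density estimation subject to relaxed feature-expectation
constraints \(|E_q[f_j] - \tilde e_j| \le \beta_j\), where \(\tilde e_j\) is
the presence-sample mean of \(f_j\).  The *regularized training gain* is
\(J(0) - J(\lambda) = \log n_{bg} - J(\lambda)\), the improvement over the
uniform model.

**Features.** Linear, quadratic, product (pairwise interactions), forward and
reverse hinge, and threshold features, all mapping scaled covariates into
\([0,1]\).  Feature classes activate with presence sample size \(m\)
following the conventional small-sample defaults: linear always, quadratic
at \(m \ge 10\), hinge at \(m \ge 15\), threshold and product at
\(m \ge 80\).  Hinge/threshold knots sit at 50 evenly spaced quantiles of
the training values (50 bounds the feature count; quantile spacing adapts to
skewed covariates such as zero-inflated neighborhood counts).  Categorical
features are deliberately absent: LULC enters as continuous focal counts.

**Regularization.** \(\beta_j = \Lambda(\text{class}, m)\, s_j / \sqrt m\),
with \(s_j\) the presence-sample standard deviation of \(f_j\) (floored at
0.01) and \(\Lambda\) the class multiplier interpolated linearly in \(m\)
and clamped at the table ends: linear/quadratic/product
\((10,30,100) \to (1.0, 0.2, 0.05)\); hinge constant 0.5; threshold
\((10,100) \to (2.0, 1.0)\).  These are an encoded approximation of the
defaults popularised by the reference maxent software; exact historical
tables differ slightly between versions.  `reg_multiplier` scales all
\(\beta_j\); 0 gives the unregularized maximum-likelihood fit used by the
oracle tests.

**Solver.** Sequential coordinate descent as in the reference maxent
algorithm: each iteration computes, for every feature, the closed-form
minimizer of a convex upper bound on the one-dimensional restriction of
\(J\) (the bound \(\log E_q[e^{\delta f}] \le \log(1 + (e^\delta - 1)
E_q[f])\) is exact for \(f \in [0,1]\), so every accepted update decreases
\(J\)), and applies the single most-improving update.  Defaults: at most 500
updates, stopping when no update can improve the gain bound by more than
\(10^{-5}\).  Presence feature expectations are smoothed into
\([\tfrac{1}{2m}, 1 - \tfrac{1}{2m}]\) (half a pseudo-count) so a feature
never observed on presences cannot drive its weight to the numerical step
cap.  Per-update gain increments are accumulated against the feature's
parent variable(s) — product increments split equally between the two
parents — and normalized to the *percent contribution* table.

**Outputs.** Raw output \(e^{\eta(x)}/Z\) sums to 1 over the training
background.  The logistic output is \(c\,q(x)/(1 + c\,q(x))\) with
\(c = e^H\), \(H\) the entropy of the fitted background density; a null
model thus scores exactly 0.5 everywhere, and typical presence sites score
near 0.5.  When projecting onto new conditions, covariates are *clamped* to
the training range, so extrapolation beyond observed conditions saturates
rather than explodes.

## The occurrence-filtering stages

Defaults encode the standard screening rules for citizen-science breeding
records: traveling counts with travel distance over 2 km and exhaustive-area
counts with search area over 100 ha are dropped (a single coordinate
misplaces such effort; comparisons are strict, so exactly 2 km / 100 ha are
retained); records are restricted to a June 1 – July 15 breeding window,
inclusive at both ends and year-agnostic; and records are spatially thinned
so no two retained points are within 20 km.  Thinning shuffles under a seed
and greedily accepts, yielding a maximal independent set of the proximity
graph — unbiased by input order and reproducible.  Distances are planar
Euclidean in projected metres (synthetic worlds are planar); a `dist_fn`
hook accepts other metrics for real projected data.  The default stage order
is protocol → season → thin; the first two commute, and every stage is
idempotent and logged.

## Study extent, background and evaluation

A per-species study extent is the union of 500-km disks around the filtered
presences (cell centres inside any disk), clipped to the domain.  Background
points — 10,000 by default — are drawn uniformly *without replacement* from
in-extent cells, avoiding duplicate covariate rows; presence cells are not
excluded by default, since background represents available environment.
Presences split 75/25 (ceiling rule on the training side) into train/test.
AUC is the rank-based (Mann–Whitney) estimate with ties counted one half.
The binarization threshold maximizes sensitivity plus specificity over the
sorted unique scores, with specificity computed against background (no true
absences exist) and ties broken toward the smallest threshold (the larger
predicted range, favouring omission-error control); a cell is suitable iff
its score is \(\ge \tau\).  The threshold is selected on test presences by
default (`threshold_on = "train"` switches).  Suitable area is reported
against both denominators — the per-species study extent and the full
domain — because restricted prediction and domain-wide reporting answer
different questions and the literature uses both.

## The twelve-run attribution design

Per species: three contemporary fits (all 14 covariates; climate +
topography; LULC + topography — topography is static in every run) and, for
each of three scenarios, three projections of the *full* contemporary model
onto clamped hybrid stacks: both families changed, climate changed with
LULC held at contemporary values, and LULC changed with climate held.  Net
range change is the percent change in suitable-cell count relative to the
contemporary full-model range, using the contemporary model's threshold.
Per-species scenario variability is summarized as min/mean/max of net
percentages across scenarios (net percentages, not areas, are averaged).
Species are stratified by how the domain truncates their true range:
`whole_range` when at least 95% of the truth range lies in the domain,
otherwise `double_truncated` when the in-domain range reaches both the
north and south domain edge rows (outermost row of the domain), else
`single_truncated`; a truncated range reaching neither edge is labelled
single-truncated with a warning, since the taxonomy has no east/west class.
Cross-species class summaries are arithmetic means over member species, and
run-configuration contrasts use the classic paired t-test.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, at
desk scale: a 200 × 200 grid of 250-m cells (a 50 km × 50 km planar world,
distances exact, no geodesy).

* **LULC** — an 8-class mosaic (water, urban, cropland, hay/pasture,
  grassland, forest, shrubland, wetland) built by seeded Voronoi
  tessellation with one 3 × 3 majority-filter pass; patch scale set by
  `spatial_autocorrelation_range` (default 10 cells ≈ 2.5 km patches,
  several focal windows wide).
* **Climate** — annual mean temperature increasing linearly from the north
  edge southwards (default 5 °C + 10 °C span) and annual precipitation
  increasing west to east (500 mm + 600 mm span), each with smooth additive
  noise (0.3 °C / 30 mm).  The compressed gradients stand in for
  continental-scale variation at desk scale.
* **Topography** — smooth random elevation (amplitude 300 m over a 15-cell
  correlation scale); slope by Horn's 3 × 3 method (degrees, edge rows
  replicated); compound topographic index \(\ln(a/\tan\beta)\) with D8 flow
  accumulation (steepest descent, ties to the lowest-index neighbor,
  accumulation in decreasing-elevation order) and \(\tan\beta\) floored at
  0.001 so flats stay finite.
* **Scenarios** — three presets mirroring the qualitative contrasts of the
  SRES storylines, applied as one transition step: A1B-like (+3.5 °C, −5%
  precipitation, urban growth 0.15, cropland expansion 0.10), A2-like
  (+4.5 °C, −10%, 0.20, 0.20), B1-like (+2.0 °C, 0%, 0.05, afforestation
  0.10).  Rates are per-eligible-cell conversion probabilities: urban grows
  into non-water cells 8-adjacent to urban, cropland replaces
  grassland/forest, afforestation replaces cropland/grassland, in that
  fixed order, one uniform draw per eligible cell in column-major order —
  exactly replayable from the scenario seed.  Published storylines are
  qualitative, so these magnitudes are the package's own calibration,
  chosen once to give visibly distinct futures.
* **Virtual species** — truth suitability
  \(S = w\,e^{-(T-\mu)^2/2\sigma^2} + (1-w)\,c/(c+h)\) mixing a Gaussian
  thermal response with a saturating response to the 5 × 5 neighborhood
  count \(c\) of a preferred LULC class, optionally zeroed above an
  elevation limit.  \(S\) is invariant to relabelling non-preferred classes.
* **Observation effort** — a mixture of Gaussian hotspots centred on urban
  cells over a uniform floor, emulating population-centred effort; records
  carry synthetic protocol metadata and dates over May 1 – Aug 31 so every
  filter has work to do.

What the generator does *not* emulate: spatial autocorrelation of residual
(non-covariate) suitability, observer heterogeneity, dispersal limitation,
temporal turnover within the record window, and geodesic geometry.  Passing
tests therefore demonstrate correctness of the machinery and recoverability
under the stated generative assumptions, not performance on real archives.

## Numerical choices and degenerate inputs

Focal windows truncate at grid edges (a corner cell of a uniform raster
counts 9 of 9 available cells) so points near study edges keep covariates;
nodata cells never contribute.  Constant covariates are dropped from the
feature space with a warning.  Zero-suitability worlds refuse presence
sampling ("no habitable cells"); `n_raw = 0` is an error, not an empty set.
An all-equal score vector thresholds at that score with sensitivity 1 and
specificity 0.  Empty presence sets pass through filters with 0 → 0 logs.
The twelve-run suite is reproducible byte-identically from one master seed;
stage seeds derive as `(seed * 101 + stage) mod (2^31 - 1)`.

## Scaling choices for the bundled demo

The full-scale defaults encode continental magnitudes (20-km thinning,
500-km buffer).  On a 50-km synthetic world a 20-km thinning radius leaves
only a handful of points, so `demo_config()` scales the thinning distance to
1 km — aggressive relative to the domain in the same way 20 km is relative
to a continent — and keeps every other default.  The demo's problem sizes
(200 × 200 world, ≈2,000 raw records per species, 10,000 background points,
three species, three scenarios) were chosen so the whole pipeline is a
desk-scale computation.

## Known limitations

* **Recovery ceiling with the historical feature defaults.**  With all five
  feature classes active (the defaults at \(m \ge 80\)), threshold and
  product features that are rarely active on presences receive very small
  penalties (\(s_j\) near zero) and inflate estimator variance when many
  covariates are irrelevant; in truth-recovery experiments, rank
  correlation with the known suitability is markedly higher when only
  linear/quadratic/hinge features are used.  Later maxent practice disables
  threshold features by default for exactly this reason; this package keeps
  the historical defaults for fidelity and exposes `feature_classes` to
  override them.
* Attribution by hybrid projection inherits the covariate-correlation
  confounds of any SDM: correlated focal counts (the eight class counts sum
  to 25) let change in a never-used class move predictions.  Attribution
  experiments should design the perturbation so the expected effect aligns
  with the species' modelled preferences.
* Thinning flattens the sampling density toward the packing limit; it
  mitigates effort bias at the cost of density information, so
  density-recovery experiments should not thin.
* The logistic output is comparable across runs of one species, not across
  species.
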