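---
title: "Methods: spatial dynamics of fire-caused tree mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial dynamics of fire-caused tree mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(firestem)
```

## The scientific problem

Dry conifer forests that historically burned every few years carried a
fine-scale mosaic of single trees, tree groups and openings. A century of
fire exclusion has filled those openings: contemporary stands are denser,
composed of smaller and more intermixed trees, with much lower crown bases.
When fire returns, the mortality it causes is filtered through that spatial
structure -- crowded neighborhoods burn hotter, low crowns torch, large
isolated trees resist -- so the *pattern* of survivors depends on the
*pattern* that burned.

`firestem` implements the statistical machinery for studying that feedback
on stem-mapped plots: second-order summaries of tree patterns and tree
marks, Monte Carlo null models with global envelope inference, a
tree-group accounting of pre- to post-fire structural change, and a
synthetic stand plus fire surrogate so the entire chain runs, end to end,
without field data or a computational fluid dynamics fire model.

## Data model

A stem map is a tibble of tree records (`id`, `x`, `y` in meters,
`species`, `dbh` in cm, optionally `height`, `crown_base_height`,
`crown_consumption`, `status`) carrying a rectangular `plot_window()`
attribute. Aspatial structure is summarized as stem density (trees/ha),
basal area (m^2/ha), quadratic mean diameter
$\mathrm{QMD} = \sqrt{\sum d_i^2 / n}$ (cm), and canopy base height taken
as the tenth percentile of tree crown base heights. The quantile uses the
linear-interpolation convention (R type 7); this choice is arbitrary but
must be fixed for reproducibility, so it is part of the contract.

Readers accept arbitrary delimited layouts through a column-mapping
argument, and an optional minimum-dbh filter mirrors census thresholds
that differ between historical (9.1 cm) and modern (10 cm) inventories.
Externally simulated fire effects join by tree id as a two-column
consumption table.

## Second-order and mark statistics

All pair statistics share one set of conventions:

* **Distance binning.** Box-kernel annuli of width 1 m with centers
  $0.5, 1.5, \dots, 14.5$ m (bins left-closed, right-open, last closed).
  No estimate is reported at $r = 0$. The 0--15 m range is where
  tree-to-tree interaction operates in these forests.
* **Edge correction.** The Ohser translation correction for rectangular
  windows: a pair with displacement $(dx, dy)$ in an $a \times b$ window
  is weighted by $1/\big((a - |dx|)(b - |dy|)\big)$, the reciprocal of the
  area over which that displacement could have been observed. It is exact
  in closed form on rectangles, with no grid approximation.
* **Estimator identity.** The production code vectorizes over a
  precomputed pair table, but it is required (and tested) to agree to
  machine precision with naive $O(n^2)$ double loops.

The statistics:

* `pair_correlation()` -- $\hat g(r)$, the density-normalized expected
  number of trees at distance $r$ from a typical tree; 1 under complete
  spatial randomness. With an `estimate_intensity()` field it becomes the
  inhomogeneous estimator (each pair weighted by
  $1/\lambda(x_i)\lambda(x_j)$, $\lambda$ looked up at the nearest 1 m
  grid cell and floored at $10^{-9}$).
* `bivariate_pair_correlation()` -- $\hat g_{12}(r)$, type-2 density
  around type-1 points; reduces bit-for-bit to the univariate estimator
  when both types are all trees.
* `mortality_difference_statistics()` -- the two contrasts for fire-killed
  trees: $g_{\mathrm{cluster}}(r) = g_{dd}(r) - g_{ad}(r)$ (are dead trees
  more common around dead trees than around survivors?) and
  $g_{\mathrm{densdep}}(r) = g_{d\cdot}(r) - g_{a\cdot}(r)$ (did dead
  trees sit in denser neighborhoods?). Both have null expectation 0 under
  random labeling.
* `r_mark_correlation()` -- mean dbh of trees found $r$ away from a tree,
  in cm, reported next to the global mean dbh: values below the mean at
  short $r$ say that close neighbors tend to be small trees.
* `mark_variogram()` -- mean of $\tfrac12 (m_i - m_j)^2$ per annulus,
  normalized by the sample mark variance so spatially independent marks
  give exactly 1 in expectation (the pair mean of the half squared
  difference over a finite population equals the $n-1$ sample variance).

Empty annuli are 0 for the pair correlations (no pairs observed) and `NA`
for the mark statistics (an undefined mean), and callers treat `NA` bins
as undefined rather than evidence.

## Null models and global envelopes

Three null models (`null_spec()`):

* **Inhomogeneous Poisson** for the patterns of living trees: points are
  redistributed with density proportional to the Epanechnikov kernel
  estimate of the observed intensity (bandwidth 20 m, resolution 1 m,
  kernel mass renormalized per tree so the field integrates exactly to
  $n$). This conditions the test on broad intensity gradients and asks
  only about second-order structure. Draws are conditioned on the
  observed count by default (an unconditioned Poisson mode exists); both
  the empirical pattern and the null draws are summarized with the same
  homogeneous estimator, so the envelope carries the inhomogeneity.
* **Random labeling** for mortality statistics: alive/killed labels are
  permuted over fixed locations, because where mortality can occur is
  conditioned on where trees stood before the fire.
* **Random marking** for dbh statistics: marks permuted over fixed
  locations.

Inference uses the studentized maximal ("st") global envelope: the
empirical and null functions are pooled, each is studentized bin-wise by
the pooled mean and standard deviation, and the critical value $c$ is the
$(n_{\mathrm{sim}}+1)(1-\alpha)$ order statistic of the pooled maxima
$\max_r |z(r)|$ (the 380th of 400 at $\alpha = 0.05$ with 399
simulations). Pooling keeps the empirical function exchangeable with the
nulls, so rejection has exactly 5% probability under the null; the band
$m(r) \pm c\,s(r)$ is back-transformed to the statistic's scale. One
excursion at any distance is significant for the whole 0--15 m range.
Degenerate bins ($s(r) = 0$) score $z = 0$ with a warning. The
`r_averaged_z` summary is the *signed* mean of the empirical $z(r)$ over
bins -- the sign carries the direction (aggregation vs inhibition,
clustering vs dispersion); the unsigned mean is also reported
(`mean_abs_z`) for readers who want magnitude only.

Permutation nulls reuse the empirical pair geometry (labels move, trees do
not), which is what makes 99--399-simulation envelopes on multi-thousand
tree maps cheap.

## The synthetic stand generator

`generate_forest()` draws a two-layer stand:

* a **Thomas cluster process** (Poisson parents, Poisson(`mu`) broods,
  Gaussian dispersal `sigma`) for the small/medium cohort. Thomas was
  chosen over other cluster processes because its pair correlation has a
  closed form, $g(r) = 1 + e^{-r^2/4\sigma^2} / (4\pi\sigma^2\kappa)$,
  which the tests use as an exact oracle. Parents live in a 4`sigma`
  buffer so boundary clusters are not thinned; offspring outside the
  window are discarded (no toroidal wrap). An optional second level
  (`parent_clustering`) makes the parents themselves Thomas-distributed,
  so the stand is aggregated both at the clump scale and at the
  clump-neighborhood scale -- without it, all aggregation sits below a
  few `sigma` and a kernel-intensity null model at 20 m bandwidth sees
  mid-range (7--15 m) *deficits* rather than the across-the-range
  aggregation characteristic of frequent-fire stands.
* a **hard-core large-tree layer**: `n_large` trees placed by dart
  throwing with minimum spacing `r_inhibit` (bounded at 10,000 attempts,
  then an error), emulating the dispersed, fire-resistant overstory.

Offspring dbh mixes a cluster-level effect with idiosyncratic lognormal
noise; `mark_coupling` is the fraction of log-dbh variance carried by the
cluster, so 0 gives location-independent marks (normalized mark variogram
1 everywhere) and values near 1 give strong size segregation. Crown base
height scales as $\mathrm{cbh} \propto d^{0.8}$ with lognormal scatter,
capped at 90% of an asymptotic height allometry.

`preset_forest_config()` freezes two calibrated parameterizations. The
**historical** preset targets the open, clumped regime: ~350 trees/ha,
QMD ~45 cm, tight clusters (`sigma` 2 m, ~40 clusters/ha of ~7 trees)
gathered into clump neighborhoods (`sigma_g` 10 m, ~4 neighborhoods/ha),
strong size segregation (`mark_coupling` 0.8), canopy base height (tenth
percentile) ~1.4 m, and ~49 large trees/ha under an 8 m hard core. The
**contemporary** preset targets the infilled regime: ~760 trees/ha,
QMD ~34 cm, weak broad clustering (`sigma` 6 m, cluster excess ~0.3 at
short range), intermixed sizes (`mark_coupling` 0.3), canopy base height
~0.7 m. These constants were set once, against the documented structural
regimes for the two eras, and then frozen; the realized summaries carry a
documented +/-10% band around those targets.

What the generator does *not* emulate matters for interpretation: there
are no broad intensity gradients (soil, topography), no species-specific
spatial niches, no regeneration or growth, and group structure at 6 m
linkage is coarser than in real historical stands (real plots held
100+ groups/ha; the presets produce fewer, larger clumps). Tests passing
on synthetic stands therefore validate the estimators and the inferential
machinery, not any claim about a particular forest.

## The fire surrogate and mortality rule

`surrogate_consumption()` stands in for a physics-based fire model with a
one-line mechanism: a tree's crown consumption (fraction of crown mass
lost) rises with the basal area of neighbors within 6 m and falls with its
crown base height,
$\mathrm{cons} = \mathrm{logistic}(a_0 + a_1 z(\mathrm{NBA}) - a_2
z(\mathrm{CBH}) + \varepsilon)$.
By default $z(\cdot)$ standardizes within the map; `preset_fire_config()`
instead fixes the centering and scaling at historical-stand reference
values, so the same fire applied to a denser, lower-crowned stand yields
systematically higher consumption -- the mechanism by which infilled
stands sustain crown fire. The preset gains ($a_0 = -0.75$, $a_1 = 1.1$,
$a_2 = 3.2$, noise 0.25) were calibrated once so that the two presets
reproduce the documented directional contrast (historical: partial,
size-biased mortality near 60%; contemporary: near-total mortality near
90% sparing dispersed large trees) and then frozen. The surrogate is a
mechanism demonstration, not a fire model: absolute consumption values
are not comparable to combustion physics output, and only the direction
and ordering of its effects are asserted anywhere.

Mortality follows the percent-scale logistic form
$p = \mathrm{logistic}(\beta_0 + \beta_1 C + \beta_2 C^2 + \beta_3 d +
\beta_4 C d)$ with $C$ crown consumption in percent and $d$ dbh in cm,
and trees with $p \ge 0.5$ classified killed. The shipped coefficient
table is deliberately labeled illustrative -- it encodes only the shape
constraints (mortality increases with consumption, decreases with
diameter, with plausible magnitudes); published species-specific
regressions are supplied by the user as a delimited table, including on
the consumption-for-scorch substitution whose scale (percent of crown
mass) the table contract declares.

## Tree groups and their dynamics

`identify_groups()` chains trees whose spacing is at or below the 6 m
limiting distance (connected components; the threshold is inclusive --
a pair at exactly 6.000 m is one group -- which is documented because it
changes toy cases). Group sizes bin into the standard classes: single,
2--4, 5--9, 10--19, 20+. `group_flow()` regroups survivors from scratch
and counts each tree from its prefire class into its postfire class or
"killed"; row sums equal prefire class totals (mass balance), and since
survivors are a subset, regrouping can split but never merge prefire
groups. Edge-truncated groups are counted whole.

`compare_group_sizes()` compares two group-size samples on location and
relative spread. Location uses the rank-sum test by default: the group
samples being compared are structurally unpaired, so the paired
signed-rank form, though named in the tradition this analysis follows, is
kept behind `paired = TRUE`. Relative spread uses a signed
likelihood-ratio test for equality of coefficients of variation under
normal models $N(\mu_i, (\tau_i \mu_i)^2)$: the deviance compares
unconstrained fits against a fit profiled over a common $\tau$ (the inner
maximization over each $\mu_i$ solves a quadratic in closed form; the
outer maximization is 1-D), and $R = \mathrm{sign}(\widehat{cv}_a -
\widehat{cv}_b)\sqrt{\mathrm{deviance}}$ is referred to $N(0,1)$. A
small-sample mean adjustment is available as `correction = "bootstrap"`
(recentering $R$ by its parametric-bootstrap null mean under the fitted
common-CV model); it is off by default because recentering breaks the
exact identity $p = 1$ for coinciding samples, and at the group-sample
sizes this package targets (dozens to hundreds of groups) the plain
signed root already holds its nominal size (verified by simulation in the
test suite). Bonferroni adjustment multiplies by the comparison-family
size, 3 by default (one comparison per plot).

## Pipeline and reproducibility

`run_scenario()` chains the stages -- generate or read the stand, simulate
or join consumption, classify mortality, test the prefire pattern
($g$ against inhomogeneous Poisson) and size structure ($k_{dbh}$,
$\gamma_{dbh}$ against random marking), the survivor pattern, and the two
mortality statistics (against random labeling), then identifies groups,
the flow matrix and the group comparison. Analysis defaults are the
study-scale settings: $r \le 15$ m in 1 m annuli, 20 m intensity
bandwidth, 399 simulations, $\alpha = 0.05$, 6 m linkage. Every random
draw derives from one master seed through a per-stage counter, so a
scenario is byte-reproducible (the serialized summary contains no
timestamps; the run log does). All outputs are delimited text or JSON so
runs can be diffed.

Problem sizes used by the automated checks: the estimator calibrations use
100 seeds of ~400-point CSR patterns and 50 seeds of ~1,600-point Thomas
patterns; type-I rates use 200 random-labeling replicates with
99-simulation envelopes and 1,000 SLRT replicates at $n = 50$; effect
recovery uses 50 seeds of the historical preset on 2.25 ha; and the
era contrast runs one full paired scenario on 4.3 ha plots (1,700--3,600
trees) with 99-simulation envelopes plus 15 lighter paired seeds for the
group claims.

## Numerical choices and degenerate inputs

* $\lambda$ floored at $10^{-9}$ before division in the inhomogeneous
  estimator; the mass-conserving renormalization makes true zeros occur
  only where no kernel reaches.
* Envelope bins with zero null variance score $z = 0$ with a warning;
  bins with undefined values are excluded from both the maximum and the
  $r$-average.
* All-dead or all-alive maps are an error for mortality statistics (the
  contrasts are undefined); constant marks are an error for the
  normalized variogram (use `normalized = FALSE`), and a valid flat
  function for the r-mark correlation.
* Coincident trees (distance 0) contribute to no pair statistic (no
  estimate at $r = 0$) but do chain into one group.
* `r_max` beyond half the shorter window side warns (variance) rather
  than errors; a surrogate-fire radius beyond the window warns (edge
  bias).

## Known limitations

The estimators assume rectangular windows (the translation correction is
closed-form only there). The package deliberately excludes fire physics,
surface-fuel crosswalks, delayed mortality and secondary mortality agents,
K/L and nearest-neighbor functions, anisotropy, and pooling across
replicated plots, and renders no Sankey diagrams (the flow matrix exports
a long-form edge list any renderer can consume). The contemporary preset's
group-size distribution is more connected than real infilled stands at
6 m linkage; conclusions about group *counts* should come from data, not
the presets.
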