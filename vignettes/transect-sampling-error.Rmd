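---
title: "Methods: sampling error of transect-based monitoring designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sampling error of transect-based monitoring designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transectopt)
```

# The question

A monitored 1-ha plot is read with three transect methods: line-point
intercept (a pin lowered at fixed intervals, recording every plant layer
it touches), canopy gap intercept (continuous segments with no plant
canopy, 5-cm minimum), and vegetation height (maximum canopy height at
fixed points). The full design — three 100-m transects laid out as spokes
from the plot center at 60° spacing, pins every 0.25 m, heights every
2 m — is the benchmark. `transectopt` quantifies how much indicator
estimates degrade when the design is reduced, and finds the lightest
design still meeting acceptable-difference criteria.

Every reduced design is obtained from the full data by three composable
operations, mirroring what a lighter field protocol would have recorded:

* `select_transects()` — keep a uniformly random subset of the transects,
  the same subset for all three methods of a plot visit;
* `truncate_transects()` — keep the portion of each transect from the
  plot center outward, clipping gap records at the cut and re-applying
  the 5-cm minimum to the clipped fragment;
* `thin_points()` — keep pins and height points on a coarser interval
  grid; gap intercept is continuous and is never thinned.

All along-transect positions are integer centimeters. Every interval in
the scenario grid is a multiple of the base intervals (25 cm for pins,
200 cm for heights), so thinning is an exact congruence filter and the
full-design scenario reproduces the full data *exactly* — this identity
is asserted in the tests and re-checked at run time by the pipeline.

# The nested limits-of-agreement model

For a design $s$ and indicator, the per-event difference is
$d_{ij} = \text{full}_{ij} - \text{sub}_{ij}$ for plot $i$, sampling
event $j$ (positive bias = the reduced design underestimates). Events
within a plot are repeat measures, so the classical Bland–Altman analysis
is fitted in nested form:

$$d_{ij} = \mu + b_i + e_{ij}, \qquad b_i \sim N(0,\sigma_b^2),\;
e_{ij} \sim N(0,\sigma_e^2).$$

Estimation, for $k$ plots with $n_i$ events each ($N = \sum n_i$):

* $\hat\mu$ = unweighted mean of the plot means $\bar d_i$. Plots are the
  inferential subjects; weighting them equally keeps a heavily revisited
  plot from dominating under imbalance. Its CI uses
  $t_{k-1}$ with standard error $\mathrm{sd}(\bar d_i)/\sqrt{k}$.
* $\hat\sigma_e^2$ = pooled within-plot variance,
  $\sum_{ij}(d_{ij}-\bar d_i)^2/(N-k)$.
* $\hat\sigma_b^2 = \max\!\big(0,\; V - \hat\sigma_e^2\,\bar m\big)$ with
  $V = \mathrm{var}(\bar d_i)$ and $\bar m = k^{-1}\sum 1/n_i$: the
  variance of plot means minus its expected within-plot share. Negative
  estimates are truncated at zero.
* Limits of agreement at level $\gamma$:
  $\hat\mu \pm z_{(1+\gamma)/2}\,\hat\sigma$ with
  $\hat\sigma = \sqrt{\hat\sigma_b^2+\hat\sigma_e^2}$.

When every plot contributes a single event ($N=k$) the within-plot
variance is inestimable; the fit then degenerates, deliberately, to the
classical unreplicated Bland–Altman analysis
($\hat\sigma^2 = \mathrm{var}(d)$), which the tests verify in closed
form. This is also the mode used by the per-plot analysis switch
(`run_scenario_grid(by_plot = TRUE)`), where a single plot's events
become the subjects.

## MOVER outer bounds

The acceptance rule looks not only at the estimated limits but at
confidence bounds on them. The bound on each limit is composed by the
MOVER principle — the limit is a sum $\mu + z\sigma$, so its bound
combines a bound on $\mu$ (t-distribution) with a bound on $\sigma$
(modified-large-sample combination of chi-square bounds for the two
variance components, on $k-1$ and $N-k$ df):

$$\text{mover}_{hi} = \hat\mu + z\hat\sigma +
\sqrt{(t\,\mathrm{SE}_{\hat\mu})^2 + z^2(\hat\sigma_{up}-\hat\sigma)^2},$$

symmetrically downward for the lower limit. The component bounds are
taken one-sided at $\gamma$, so the outer bound covers the true limit
with probability $\gamma$ — the calibration the tests certify by Monte
Carlo (2000 replicates at $k=13$, $n_i\in[5,20]$, both levels, observed
coverage within ±2 points of nominal). We treat this coverage property,
not any particular algebraic transcription, as the definition of
correctness for the bound. The bounds are labelled agreement-limit
confidence bounds; no separate prediction-interval formula is exposed.

## Acceptance criteria and design selection

A design cell passes when (1) the bias CI contains zero and (2) the
larger of $|\text{mover}_{lo}-\hat\mu|$, $|\text{mover}_{hi}-\hat\mu|$
is within the family threshold: 5 percentage points for cover and the
gap classes, 5 cm for height, 2 species for the species count — the
standard field-crew calibration limits. Both the agreement proportion
and the confidence level are read as the same $\gamma$ (0.80 or 0.95);
they are separate knobs internally for sensitivity checks.

`select_minimum_design()` orders effort lexicographically: total transect
length first, then measurement count. Laying out and walking transects is
the dominant field cost, and this ordering also reproduces the published
headline choices for LPI (e.g. two 100-m transects at 0.5 m beating both
two 100-m at 0.25 m and three 100-m at 1 m). Because ties and trade-offs
are real, the Pareto-minimal passing set on (length, measurements) is
reported as alternates. Gap intercept has no measurement interval, so its
second effort axis is the number of transect lines read; this lets two
designs with different lengths but different line counts coexist as
alternates rather than collapsing to the shortest.

# The synthetic plot network

Real network data cannot ship with the package, so `generate_study()`
simulates a network with the structure the analysis assumes. Defaults
(all tunable via `synthetic_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_plots` | 13 | plots in the network |
| `events_min`–`events_max` | 5–18 | sampling events per plot (drawn uniformly; ~150 events per study) |
| `cluster_mu` | 8 | plants per Thomas cluster |
| `cluster_sd_cm` | 300 | cluster spread; `Inf` = homogeneous Poisson |
| `radius_meanlog`, `radius_sdlog` | log 60, 0.4 | lognormal canopy radii (cm) |
| `cover_range` | 0.02–0.95 | Boolean-cover targets spanned by the plot gradient |
| `sigma_plot` | 0.25 | lognormal SD of the per-plot intensity multiplier |
| `sigma_event` | 0.15 | fraction of plants moved/re-drawn per event |

Choices worth explaining:

* **Geometry.** Transects are modeled as three 100-m directed spokes from
  the plot center (positions 0 → 10000 cm), because subsampled lengths
  run from the center outward; the simulated plant map covers the full
  spoke extent plus a canopy-radius buffer. The "1 ha" of the plot name
  describes the nominal monitored area, not the map extent.
* **Thomas clusters, not bare Poisson.** Sampling error at coarse pin
  spacing depends on whether pins skip over plant clusters, so clustering
  must be tunable; the Poisson (Boolean) model remains available as the
  `cluster_sd_cm = Inf` special case and is the regime with a closed-form
  coverage probability, $1-\exp(-\lambda\pi E[r^2])$, used as a simulator
  oracle in the tests.
* **Sparse-to-dense gradient.** Per-plot canopy intensity follows a
  log-spaced gradient between the `cover_range` targets (playa-like
  near-zero cover up to ~95%), jittered by the plot random effect. This
  gives the between-plot variance the nested model partitions, and spans
  the cover range over which the acceptance thresholds are meaningful.
* **Event perturbation, not redraws.** Each event moves and re-draws a
  fraction `sigma_event` of the base map's plants. Independent redraws
  would make events exchangeable with fresh plots; partial perturbation
  creates the within-plot correlation that makes the nested analysis
  matter (the tests show a naive pooled bias CI collapses to ~45%
  coverage on such data while the nested CI stays near nominal).
* **Virtual crew.** A pin intercepts a plant when the pin's plot
  coordinates fall inside the canopy disk; layer codes are species sorted
  by height (top canopy first), `"NONE"` when nothing is hit. Gaps are
  the complement of the union of canopy chords, rounded inward to whole
  centimeters and kept at ≥5 cm. Heights record the maximum intercepting
  canopy height, absent when no plant is hit — and mean height
  consequently excludes plantless points rather than imputing zero: it is
  the mean height of plants, not of points. An indicator with no valid
  input for an event is `NA`, never 0, and differences exclude such
  events pairwise.

What the simulator does **not** emulate: seasonal or directional trends
within a plot (events are exchangeable replicates, as the nested model
assumes), observer error, dead/live distinctions, elliptical canopies,
and real species assemblages. Tests passing on synthetic studies
therefore certify the machinery — exact subsampling, correctly
partitioned variances, calibrated bounds, reproducible seeds — not the
ecological values of any particular network; numeric results on real
data will differ with the vegetation structure.

# Numerical and degenerate-input conventions

* Integer-centimeter positions everywhere; class membership of a gap is
  by its integer length (24 cm → 5–24 class, 25 cm → 25–50 class), and
  the "51–100" labelling resolves the ">50–100" convention at whole-cm
  resolution.
* A gap clipped by truncation is kept only if the fragment is ≥5 cm,
  matching the field rule that gaps terminate at the transect end.
* Negative variance-component estimates truncate at zero; with all
  differences identical the fit collapses cleanly (zero half-width,
  MOVER bounds equal to the bias).
* Transect subsets derive from the master seed through per-(plot, event,
  scenario) hash streams (`derive_seed()`), so adding scenarios or plots
  never perturbs existing draws and reruns are byte-identical.
* Shapiro–Wilk normality diagnostics are reported per indicator × design
  but never gate the analysis; constant difference sets are reported as
  undefined.
* Height measurement intervals accept any multiple of 2 m; the default
  grid (2, 4, 8, 16, 20 m) follows the standard reporting grid for this
  analysis rather than the evenly spaced alternative.

# Problem sizes

The default study is 13 plots × 5–18 events (~150 plot visits, ~1200
pins each). The shipped analysis scripts and the acceptance script run
this full size. The test suite uses the same defaults for the end-to-end
qualitative checks (20 seeded studies for the effort-vs-precision trend)
and the stated Monte-Carlo sizes for the statistical calibration checks
(2000 replicates for MOVER coverage, 500 for bias-CI coverage, 50 plots
for the Boolean-model oracle, 200 randomized fixtures for the indicator
oracles); structural unit tests use smaller studies where size is
irrelevant to the property under test.

# Known limitations

* The agreement analysis assumes normally distributed differences;
  species-count differences are integer-valued and bounded below by the
  subsampling monotonicity, so their limits are approximations at very
  low richness.
* The design selector's effort ordering (length, then measurements) is a
  modeling choice; programs whose costs are dominated by measurement
  time can re-rank the reported Pareto set.
* Only the radial spoke layout is implemented; parallel or offset
  transect configurations, landscape-level (multi-plot) allocation, and
  minimum-gap-size variation for gap intercept are out of scope.
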