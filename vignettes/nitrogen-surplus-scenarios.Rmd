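---
title: "Nitrogen surplus budgets, typologies and 2030 reduction scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrogen surplus budgets, typologies and 2030 reduction scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsurplus)
```

## The problem

The EU Green Deal's Farm to Fork strategy aims to halve nutrient losses by
2030, operationalized here as a 50% reduction of the agricultural nitrogen
(N) surplus — the excess of N inputs over harvest removals on the
soil–plant system, the standard proxy for potential N losses to air, water
and soil. Whether a given input-reduction policy (for instance the
headline 20% fertilizer cut) can reach that target depends on the regional
structure of the N balance: manure-dominated landscapes respond to a
fertilizer lever very differently from fertilizer-dominated ones.

`nsurplus` implements the full analysis chain for this question on
regional, ensemble-structured N budget data: budget accounting, typology
classification, yield-response fitting with technology extrapolation, and
2030 scenario projection, plus a synthetic data generator so that every
stage can be exercised and validated offline.

## The N budget

For region $i$, year $y$, ensemble member $m$ and sector
$s \in \{\text{agricultural}, \text{non-agricultural}\}$:

$$\mathrm{Surp} = (\mathrm{In}_{\mathrm{fert}} + \mathrm{In}_{\mathrm{man}}
+ \mathrm{In}_{\mathrm{dep}} + \mathrm{In}_{\mathrm{bnf}})
- (\mathrm{Out}_{\mathrm{crops}} + \mathrm{Out}_{\mathrm{past}})$$

with all fluxes in kgN per hectare of the sector's reference area per
year, and NUE $= 100\,\mathrm{Out}/\mathrm{In}$ (%). The budget is a soil
surface balance: manure is counted as applied to soil. Two per-ha
normalizations coexist and are kept explicit throughout: agricultural
surplus per hectare of agricultural area (scenario work), and total
surplus per hectare of total area (typology classification).

Uncertainty is carried as a 16-member ensemble crossing 2 fertilizer, 4
manure and 2 pasture-removal reconstructions (`ensemble_key()`). Headline
values use the member-mean series; uncertainty bands are min–max over the
members. Because the budget is linear in its components, the surplus of
the member-mean components equals the member-mean surplus — a property the
tests assert exactly.

Design choices worth stating:

* Negative surpluses are retained and flagged via NUE > 100%, never
  floored — the identity is a pure balance.
* Areas may vary by year; aggregation and phase summaries use the
  year-specific areas by default (a fixed-area option exists in
  `phase_summary()` because published mass aggregates do not always state
  which convention they use).
* Mass conversions use 1 TgN = 10^9 kgN. Shares are rounded to whole
  percent only in the report stage, never internally.

## Typology classification

Regions are classified from their centennial trajectories: decadal means
(1850s–2010s, 17 decades) of twelve variables — the two fertilizer
reconstructions, four manure reconstructions, fixation, deposition, the
two output reconstructions, and the agricultural and non-agricultural
areas. The trajectories are kept (12 × 17 = 204 columns) rather than
averaged away, because the classification targets long-term developments,
not a modern snapshot; a flattened feature vector preserves the timing of
intensification, which separates regional archetypes that a centennial
mean would blur.

Each column is z-scored (population standard deviation) since the
variables span orders of magnitude; columns constant up to rounding are
dropped with a warning. Centres and scales are stored on the returned
matrix for inversion.

The classifier is a 2×2 batch self-organizing map. Batch mode — assign
all points to their best-matching unit, then blend each node toward the
Gaussian-neighborhood-weighted data mean — was chosen over online
training because its updates are order-invariant sums, making the
partition reproducible and independent of row order. Defaults: 500
epochs, neighborhood radius decaying 1 → 0.1 grid units, learning rate
0.5 → 0.01, and deterministic initialization on the plane of the first
two principal components (random initialization is available and is the
only consumer of the seed). An empty node at convergence is a warning,
not an error. A zero radius restricts updates to the best-matching node;
a zero learning rate leaves weights at their initialization — both are
exercised as degenerate cases in the tests.

The node count is validated with the Davies–Bouldin index (mean over
clusters of the worst-case $(S_i + S_j)/M_{ij}$ ratio; lower is better).
`select_k()` scans candidate counts 2–6 on 1×k or near-square lattices
and flags the most parsimonious minimum; identical centroids raise an
error rather than dividing by zero.

Nodes are mapped to labels by explicit rules: lowest agricultural-area
fraction → NAT (natural landscapes); among the rest, highest mean manure
share of inputs → MAN, highest fertilizer share → FERT, remainder → MOD.
A node winning both MAN and FERT is resolved by surplus magnitude
(highest surplus keeps MAN) and otherwise raises an error carrying the
per-node diagnostics. NAT is excluded from all downstream agricultural
analysis, after labelling.

## Yield response and technology extrapolation

N output responds to N input through the one-parameter hyperbolic
saturation

$$\mathrm{Out} = \frac{c\,\mathrm{In}}{c + \mathrm{In}},$$

where $c$ (kgN ha^-1 yr^-1) is the asymptotic maximum achievable output
under the prevailing technological and management practices (TMPs).
Given window-mean input and output, the coefficient has the closed form
$c = \mathrm{In}\cdot\mathrm{Out}/(\mathrm{In} - \mathrm{Out})$, which
reproduces the window mean exactly; it is defined only for
$0 < \mathrm{Out} < \mathrm{In}$ and errors otherwise. The window-mean
closed form is the default because inputs and outputs enter the analysis
as period averages; a least-squares fit to the annual points within the
window is available behind `method = "annual"`.

Two TMP modes drive 2030 projections:

* **same TMPs** — $c$ stays at its 2015–2019 baseline value;
* **improved TMPs** — $c$ is refitted on eight windows (1981–1985, …,
  2011–2015, 2016–2019), regressed linearly on the window midpoint year
  (midpoints 1983, …, 2017.5 — the arithmetic mean of the window
  endpoints), and extrapolated to 2030:
  $c(2030) = c_{\text{baseline}}(1 + \Delta c_{\mathrm{TMP}})$.

The 95% interval on $c(2030)$ is the confidence interval of the *mean
response* of the linear fit (t distribution, 6 df), not a new-observation
prediction interval: the uncertainty being propagated is that of the
technology trend line itself. Note the deliberate asymmetry, mirrored
from the source conventions: the last trend window is 2016–2019 while
the baseline $c$ uses 2015–2019.

The inverse question — what input level yields a target surplus — has the
closed form $\mathrm{In} = (S + \sqrt{S^2 + 4cS})/2$, the positive root
of $\mathrm{In}^2/(c + \mathrm{In}) = S$. Tests check it against an
independent fine-grid search to 1e-6 relative tolerance.

Response coefficients are fitted on area-weighted scope aggregates
(typology, country or EU-27), not per region: the scenario logic operates
at those scopes, and per-region fits would be undefined wherever output
locally exceeds input.

## Scenario engine

Five named scenarios reduce baseline-window (2015–2019) inputs —
GD-F (20% fertilizer), FAO-F (43% fertilizer), FAO-FM (43% + 4% manure),
BAF (20% + 10% manure), LAP (20% + 20% manure) — with deposition and
fixation never reduced. The projection is purely the hyperbolic response:
reduced inputs, $c$ resolved by TMP mode, output predicted, surplus the
difference, reductions in percent of baseline.

Business-as-usual is different in kind: a penalized thin-plate regression
spline GAM of the 1961–2019 surplus extrapolated to 2030. A count-data
(negative-binomial, log-link) family is applied, which requires
integer-like data; the surplus is rescaled by a factor (default 100) and
rounded before fitting, and the prediction unscaled. Because applying a
count family to continuous data is a modelling convention rather than a
necessity, a Gaussian identity-link fit is also implemented and engaged
automatically whenever the series contains non-positive values (where the
log link is undefined). An increase appears as a negative reduction.

The bottom-up analysis evaluates the same projection over the full
fertilizer × manure reduction plane at a 1% step (101 × 101 cells — the
published range is 0–100% with no stated resolution; 1% makes the named
scenarios exact grid cells, which the tests assert). The 50% contour is
extracted by linear interpolation between bracketing cells and
cross-checked against the analytic inversion; the target zone combines
fertilizer reduction ≥ 20% with surplus reduction in [50%, 100%]. Both
surfaces are monotone non-decreasing in both axes, and improved TMPs
dominate same TMPs cell-wise whenever $c(2030) > c_{\text{baseline}}$ —
both asserted over the whole grid.

Ensemble propagation reruns the entire chain (baseline means, baseline
$c$, trend, projection) independently per member and reports the min–max
band around the member-mean headline. Reductions are scale-invariant:
scaling all of a member's components by a common factor scales $c$ and
the fluxes alike and leaves the percent reduction unchanged, which the
tests verify numerically.

The EU-27 bottom-up curve uses an EU-level $c$ fitted on EU aggregates
(rather than aggregating typology-level results); the typology route is
available by running the grid per typology and combining downstream.

## The synthetic generator

The generator emulates the study conditions end to end: 393 regions over
1850–2019 with the 16-member ensemble, drawn from four archetypes in
EU-like proportions (MAN 22%, FERT 30%, MOD 33%, NAT 15%). Each input
component follows a logistic rise (base + amplitude, midpoint, time
scale) damped after 1985 by an exponential relaxation — the two-phase
rise-then-decline shape of the historical record, with the aggregate
surplus peaking near 1985. Decline rates exceed the logistic growth rate
remaining at 1985 for every component, so the post-1985 decline holds
per region, not just on average. Archetypes differ in both input shares
(MAN manure share 55–72% across the record; FERT fertilizer-heavy with
historically large fixation; NAT agricultural-area fraction 0.08) and in
the *timing* of intensification (MOD intensifies about a decade later
than FERT): a pure amplitude contrast would be erased by the region-level
scale heterogeneity, while timing differences survive z-scoring.

Outputs are generated from inputs through the hyperbolic response with a
coefficient drifting logistically upward with the intensification era
(flat at a historical base before ~1950, approaching a modern plateau),
so the response-fitting assumptions of the downstream stages hold by
construction and recovery tests are meaningful. The logistic drift, not a
linear one, keeps simulated NUE inside its historical band (20–80%) in
the quiet early decades as well.

Stochastic structure: one lognormal scale factor per region (sdlog 0.15)
applied coherently to input amplitudes *and* to the response coefficient
(so regional NUE stays well-posed), smaller per-component lognormal
factors (sdlog 0.075) that vary the share profile, and year-level
multiplicative observation noise (sdlog 0.05). The ensemble arises by
scaling fertilizer input, manure input and pasture removal by
variant-specific factors (±6%, ±12%, ±8% spreads). All draws flow from a
single seed; a fixed seed gives byte-identical tables.

What the generator does **not** emulate: spatial (gridded) structure and
autocorrelation between neighbouring regions, country-level policy
breaks, trade effects, or any real historical magnitudes. Passing tests
demonstrate that the pipeline's algorithms are correct and internally
consistent under data with the assumed structure — not that the published
headline numbers are reproduced; those depend on the archived historical
dataset, which this package deliberately does not bundle.

## Numerical choices and degenerate inputs

* Squared-distance computations are clamped at zero before square roots
  (floating cancellation on near-duplicate points).
* Feature columns are "constant" when their population sd is below
  1e-10 relative to their mean.
* Davies–Bouldin ties in `select_k()` are resolved toward the smallest
  node count (a larger map converging with empty nodes onto the same
  partition produces exact ties).
* `fit_c` refuses non-positive surplus (Out ≥ In) and non-positive
  output; scopes hitting this in batch drivers are excluded with a
  warning, not silently dropped.
* The BAU count rescaling factor (100) keeps three significant digits of
  a per-ha surplus in the integerized series; the projection is
  insensitive to it over 10–1000.
* Percent changes between phases are computed on 3-year window means
  (the 3-year moving average centred in the window) and refuse a zero
  start value.

## Problem sizes

The test suite runs the full pipeline on a 12-region fixture (3 regions
per archetype, full 1850–2019 years and all 16 members) and the recovery
analysis on 120 regions; both are regenerated from code at test time.
The acceptance script runs the complete study conditions (393 regions).
These sizes give stable statistics while keeping a full run in tens of
seconds on a single CPU.

## Worked example

```{r, eval = FALSE}
library(nsurplus)

sim <- simulate_budget(generator_config(seed = 1))
budget <- compute_surplus(sim$records)

feats <- build_features(sim$records)
som <- train_som(feats)
typ <- label_typologies(som, sim$records)

series <- member_mean(
  aggregate_budget(budget, "typology", typ$assignment, "agricultural"))
series <- series[series$scope_id != "NAT", ]

run_scenarios(series)                       # named scenarios, both TMP modes
run_bau(series[series$scope_id == "FERT", ])  # trend extrapolation
```

## Known limitations

* The typology labelling rule assumes the four archetypes are actually
  present; exotic partitions (e.g. two manure-dominated nodes) trigger
  the collision error rather than a heuristic guess.
* The technology trend is a straight line through eight points; it is a
  moderate, evidence-shaped extrapolation, not a forecast, and its 95%
  band quantifies only the line's uncertainty.
* N-loss pathway partitioning (leaching, volatilization, denitrification)
  and economic/trade feedbacks are out of scope.
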