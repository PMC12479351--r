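---
title: "Methods: multi-objective land-use reallocation with tripleland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective land-use reallocation with tripleland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripleland)
```

## The problem

Rural land serves three competing objectives: sequestering carbon, producing
food and timber, and hosting biodiversity. On a gridded landscape where every
cell currently carries one of four land-use categories (arable, pasture,
plantation forest, semi-natural habitat) and can be converted to any of the
others, which conversions are worth making, and how do the three objectives
trade off? `tripleland` answers this with a cell-separable multi-objective
optimisation: pre-computed per-cell benefit maps, a weighted-sum scan over a
discrete simplex of objective weightings, optional conversion budgets, and
ensemble analyses (Pareto frontiers, strictly-better sets, conversion-frequency
maps) over the resulting scenarios.

## The model

### Benefit maps

For every cell $n$ and target category $k$ a raw benefit is computed for each
objective $O \in \{C, P, B\}$, giving 12 maps (4 categories x 3 objectives).

**Carbon** (t CO$_2$-eq yr$^{-1}$ per cell) combines:

* the one-off soil+vegetation stock change
  $(\mathrm{stock}_k - \mathrm{stock}_{\mathrm{current}}) \times 44/12$
  (t C ha$^{-1}$ to t CO$_2$-eq ha$^{-1}$), amortised linearly over the
  30-year planning horizon. Amortisation over the horizon is a package
  decision: it makes one-off stock deltas commensurable with the recurring
  annual terms, and matches the 2020--2050 window over which forest
  sequestration is averaged. Keeping the current category has zero stock
  change by construction.
* recurring annual terms attached to the target state: fertiliser
  N$_2$O on arable land (default 1460.67 g N$_2$O-N ha$^{-1}$ yr$^{-1}$,
  converted by the stoichiometric factor 44/28 and GWP-100 of 273 to
  626.63 kg CO$_2$-eq ha$^{-1}$ yr$^{-1}$) and livestock emissions on
  pasture (default 7.62 t CO$_2$-eq ha$^{-1}$ yr$^{-1}$, a national average
  herd mix applied uniformly — the package treats these as *state* costs, not
  transition costs, so they apply whatever the origin category was);
* peat-state fluxes on peaty soils, keyed by the *target* category: drained
  agricultural peat emits strongly, rewetted semi-natural peat sequesters a
  little. The literature the analysis leans on gives no single printed
  number, so the defaults (−24, −18, −8, +2 t CO$_2$-eq ha$^{-1}$ yr$^{-1}$
  for arable, pasture, plantation, semi-natural) are package choices at the
  magnitudes typical of published drained-peat emission factors, and fully
  configurable;
* mean annual forest sequestration over the horizon, from a yield-class
  growth curve. Plantation sequestration is multiplied by the share of
  harvested-wood carbon stored long-term (default 0.482); broadleaved
  semi-natural woodland is not harvested and keeps the full rate.

The yield-class curves themselves are configurable; the default is a logistic
cumulative-sequestration curve whose asymptote scales with yield class
(managed conifers: faster, earlier midpoint; broadleaves: slower, later).
This collapses stand-age structure, thinning and time-to-felling into a
single mean annual rate, which is the granularity the cell-separable
optimisation needs.

**Production** (GBP yr$^{-1}$ per cell): the arable revenue surface (after
outlier filtering, below) times cell area; pasture revenue zeroed where the
suitability index is under 20 (the threshold is "under": an index of exactly
20 still produces); plantation timber revenue derived from the growth curve
(rate / (44/12) / carbon density x timber price); semi-natural habitat
produces nothing.

**Biodiversity** (unitless, in [0, 1]): per-species occurrence probabilities
are summed per cell and category, min--max normalised *globally* over all
cells and categories, and combined with a land-use-specific habitat condition
score by geometric mean, $\sqrt{S_{\mathrm{norm}} \cdot \mathrm{condition}}$.
Condition defaults: arable 0.08, pasture 0.10, plantation 0.23, newly created
semi-natural 0.33, and established semi-natural by sub-habitat (natural
grassland 0.30, heath 0.45, fen/bog 0.55, broadleaved woodland 0.70 — the
0.38--0.70 band for established habitats is table-driven and configurable).
Established habitat outranking newly created habitat encodes the time
habitats need to mature.

**Future sub-habitat.** A cell converted to semi-natural habitat becomes the
sub-habitat of its nearest existing semi-natural cell (Euclidean distance
between cell centres; first donor in column-major order on ties), except that
peaty-soil cells always become fen/bog — peat restoration is prioritised over
the nearest-neighbour result. If a landscape has no semi-natural cell at all,
the peat cells themselves (forced to fen/bog) act as donors; with neither the
assignment is an error.

**Outlier filtering.** The arable revenue surface is cleaned with an
interquartile-range rule: cells outside $[Q_1 - 1.5\,\mathrm{IQR},\,
Q_3 + 1.5\,\mathrm{IQR}]$ are replaced by the mean of their finite,
non-outlier 8-neighbours (Moore ring; boundary cells use what exists).
Numerical edge cases are pinned down as follows: a constant surface has zero
IQR and nothing is flagged (avoiding degenerate mass replacement);
replacements are computed from the original values, so one replacement never
feeds another; a flagged cell with no valid neighbour falls back to the mean
of all valid cells.

### Optimisation

Raw benefits are min--max normalised per objective over all cells and all
four categories (global normalisation; a per-cell alternative reading would
erase the spatial signal that makes frontier analysis meaningful, and is not
offered). For a weighting $w = (w_C, w_P, w_B)$, integer percents summing to
100, the per-cell score is

$$b_{n,k} = \bar b^C_{n,k}\,\tfrac{w_C}{100} + \bar b^P_{n,k}\,\tfrac{w_P}{100}
          + \bar b^B_{n,k}\,\tfrac{w_B}{100},$$

and the scenario takes $k_n = \arg\max_k b_{n,k}$ in every convertible cell.
Because the aggregate is a sum over cells, the per-cell argmax is globally
optimal — the test suite checks this against exhaustive search over all
$4^n$ allocations on small grids. Argmax ties prefer the incumbent category
(no phantom conversions at zero gain), then the fixed order arable < pasture
< plantation < semi-natural. Weights are kept as integer percents so simplex
enumeration and group membership are exact; they only become fractions inside
the scalarization.

The full scan uses the step-5 simplex: 231 weightings. Weightings are grouped
as carbon- / production- / biodiversity-prioritising (that weight $\ge 50$)
or balanced (all $\le 50$); boundary weightings belong to both their
objective group and the balanced group, and each group then contains exactly
66 weightings. Read literally, the rules place a (50, 50, 0) weighting in
*three* groups (both objective groups and balanced); the group-size identity
still holds and the package keeps that literal reading.

### Conversion budgets

With a budget $\beta$, cells are converted greedily from most to least
beneficial, where a cell's merit is its improvement delta
$b_{n,k^\*} - b_{n,\mathrm{current}}$. Only strictly positive deltas are
candidates — a cell whose best use is its current use is never converted, so
the realized conversion rate can sit below the budget. The number of
conversions is $\lfloor \beta \cdot n_{\mathrm{convertible}} \rfloor$ (floor,
never exceeding the stated budget; cells and hectares coincide because all
cells share one area). Equal deltas at the cut are ordered by a seeded
uniform shuffle, so a scenario is reproducible from its seed and two seeds
can differ only on tied cells. Budgets count cells, and because each budget's
selection is a prefix of the same ranked list, the aggregate weighted benefit
is non-decreasing in the budget.

### Ensemble analyses

Scenario performances (per-objective sums of raw benefits over convertible
cells) are normalised against aggregate bounds: the sum of per-cell minima
(maximum) across categories, i.e. the performance if that objective alone
were minimised (maximised) with unlimited conversion. Corner weightings
reproduce the maxima exactly. On the normalised triples the package extracts
the non-dominated set (weak dominance: another point $\ge$ everywhere and
$>$ somewhere; duplicates kept once), pairwise two-objective frontiers
(monotone staircases, sorted by the first objective), axis-parallel and
guarded distances from the current state to the scenario cloud
(`constrained_improvement`, over the discrete scenario set — an interpolated
frontier is a plotting convenience, not a measurement), and the
strictly-better set (all three objectives $\ge$ the current state's; the weak
inequality is deliberate, "better or equal").

Robustness is summarised by per-cell conversion frequencies over the
unlimited-budget ensemble, overall and per priority group; shares are
reported relative to the full ensemble so the four category shares plus the
unchanged share sum to one per cell.

## The synthetic landscape generator

The generator is first-class, tested code: it defines the study conditions
under which everything downstream is validated. It emulates the *statistical
structure* of the national input stack, not its geography:

* land cover: white noise smoothed with a Gaussian kernel (sd =
  `correlation_length` cells), rank-thresholded at the requested share
  quantiles. Default shares 25.77% arable, 31.59% pasture, 6.49% plantation,
  36.15% semi-natural; realized shares are exact up to integer rounding.
* peat: a second smoothed field with an additive bias on semi-natural cells,
  so peat co-locates with bog/fen-like cover; default 10% of cells.
* sub-habitats: peat cells are fen/bog; remaining semi-natural cells split
  35/20/45 between grassland, heath and broadleaved woodland along a third
  smoothed field.
* surfaces: arable revenue 400--900 GBP ha$^{-1}$ yr$^{-1}$ with a small
  configurable fraction of extreme outliers (exercising the IQR filter),
  pasture suitability 0--100, pasture revenue 250--600 GBP ha$^{-1}$
  yr$^{-1}$, forest yield class 4--24.
* occurrence: per species, a smoothed field in [0, 1] scaled by a
  per-species category affinity and clipped; the default affinities give
  semi-natural habitat the highest mean probability, plantation intermediate,
  arable the lowest.

No published source states the spatial covariance of any of these inputs, so
the correlation length (default 3 cells) and the surface ranges are free
parameters of the generator, chosen once at realistic magnitudes and
documented here; they are not tuned against test outcomes.

What the generator does *not* emulate: climate gradients, real species
ranges, the spatial coherence of administrative regions, price dynamics, or
any correlation between yields and land-cover history beyond what smoothing
induces. Passing tests therefore demonstrate the correctness and internal
consistency of the *method* — optimality, monotonicity, determinism, frontier
geometry — not the reproduction of any national map or headline national
statistic, which would require the original datasets.

## Problem sizes and determinism

The test suite runs the oracle comparisons on 6--8-cell grids (where
exhaustive search over $4^n$ allocations is feasible), the frontier and
budget-monotonicity properties on 50 x 50 landscapes with the full
231-weighting scan, and end-to-end determinism on 20 x 20; the acceptance
script uses a 50 x 50 landscape with all 12 default budgets. These sizes were
chosen so the whole suite completes in minutes while the grids remain large
enough for the statistical contracts (share calibration, frontier shape) to
bind. Every random draw flows from an explicit seed: landscapes are a pure
function of their configuration, and budget tie-breaks take a per-scenario
seed derived from the pipeline seed, so reruns with an identical
configuration are byte-identical.

## Known limitations

* The model is cell-separable by construction: no connectivity, adjacency or
  landscape-scale interactions enter the biodiversity indicator or the
  optimiser.
* Conversion costs, time lags to habitat establishment, dietary or market
  feedbacks, and urban expansion are out of scope.
* Livestock emissions and the wood-product share are single national
  constants; spatial variation would need user-supplied surfaces.
* The rasters are plain-text ASCII grids with an arbitrary coordinate frame;
  the package does not handle projections or geo-referencing.
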