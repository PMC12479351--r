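# tripleland

Multi-objective rural land-use reallocation: carbon sequestration, food and
timber production, and biodiversity on one gridded landscape.

## What it does

Land policy has to serve three objectives at once — sequester carbon, produce
food and timber, and host biodiversity — and land conversions trade them off
against each other. `tripleland` explores that trade-off space exhaustively
instead of evaluating a handful of hand-picked scenarios. On a grid where
every cell carries one of four land-use categories (arable, pasture,
plantation forest, semi-natural habitat) and can be converted to any of the
others, the package:

1. builds **12 benefit maps** — the raw benefit of converting each cell to
   each category, for each objective: carbon in t CO₂-eq/yr (stock-change
   amortised over a 30-year horizon, fertiliser and livestock emissions,
   peat-state fluxes, forest growth with a long-term wood-product share),
   production in £/yr (crop revenue with IQR outlier filtering, pasture
   revenue gated by a suitability threshold, timber revenue), and a 0–1
   biodiversity indicator (summed species occurrence probabilities, globally
   min–max normalised, combined with habitat condition scores by geometric
   mean);
2. scans the **weight simplex**: all integer-percent weightings
   `(w_C, w_P, w_B)` summing to 100 at step 5 — 231 weightings. Per weighting
   the scalarized score of cell *n* under category *k* is

   ```
   b[n,k] = bC[n,k]·w_C/100 + bP[n,k]·w_P/100 + bB[n,k]·w_B/100
   ```

   and the optimal scenario takes `k[n] = argmax_k b[n,k]` in every cell —
   globally optimal because the aggregate objective is cell-separable;
3. applies **conversion budgets**: cells are converted greedily by improvement
   delta, most to least beneficial, until `floor(budget × n_cells)` cells are
   converted or no cell with positive gain remains (so the realized conversion
   rate can sit below the budget), with seeded random tie-breaking;
4. analyses the scenario ensemble: performance normalisation against the
   objective-wise best/worst aggregate bounds, **Pareto frontiers** (3D
   non-dominated set and pairwise staircases), axis-parallel distances from
   the current state to the frontier, the **strictly-better set** (scenarios
   at least as good as today in all three objectives), and per-cell
   **conversion-frequency maps** overall and within the four priority
   weighting groups (carbon/production/biodiversity ≥ 50, balanced ≤ 50; 66
   weightings each).

A seeded synthetic landscape generator stands in for the national land-cover,
yield, peat and species-occurrence datasets, so the entire pipeline is
reproducible and testable offline. Real rasters can be exchanged through
plain-text ASCII grids.

## Worked example

```r
library(tripleland)

cfg <- pipeline_config(synth_config(n_rows = 40, n_cols = 40, seed = 42),
                       step = 5L, budgets = c(0.01, seq(0.1, 1, 0.1)))
run <- run_pipeline(cfg, quiet = TRUE)
print(run)
summary(run)
```

```
Land-reallocation run: 2541 scenarios (231 weightings x 11 budgets) on 40 x 40 cells
  current normalized performance: carbon 0.489, production 0.503, biodiversity 0.494
  Pareto-flagged scenarios: 2539; strictly better than current: 43
2541 scenarios; current normalized performance (C, P, B): 0.489, 0.503, 0.494
unlimited-budget conversion rates: 51.4% to 75.1%
strictly better than current (unlimited budget): 4 scenarios
  carbon: axis-parallel gain +0.278 (normalized) over current
  production: axis-parallel gain +0.058 (normalized) over current
  biodiversity: axis-parallel gain +0.031 (normalized) over current
```

Reading this: the current (synthetic) land allocation reaches about half of
what each objective could achieve if land were reallocated to serve it alone
(0 = objective minimised, 1 = maximised, under unlimited conversion). Only 4
of the 231 unlimited-budget weightings produce scenarios that are at least as
good as the current state in *all three* objectives at once — improving
everything simultaneously requires carefully placed conversions, not just any
conversions. The axis-parallel gains say how much each objective could improve
without worsening the other two. Per-budget scenario rows carry the raw and
normalised performance triples, conversion rate, priority groups and
Pareto/strictly-better flags:

```
  w_C w_P w_B budget carbon_norm production_norm biodiversity_norm conversion_rate is_pareto
1   0   0 100   0.01   0.4938522       0.4932965         0.5036466            0.01      TRUE
2   0   0 100   0.10   0.5336534       0.4028592         0.5883016            0.10      TRUE
3   0   0 100   0.20   0.5881490       0.3059227         0.6779536            0.20      TRUE
4   0   0 100   0.30   0.6572269       0.2183308         0.7635117            0.30      TRUE
```

`plot(run)` draws the three pairwise Pareto panels (scenario cloud, frontier
staircase, current state); `run$frequency$all` and the per-group maps show
where conversions are robust to changing priorities. `write_run_outputs(run,
dir)` exports everything as CSV and ASCII grids, and
`inst/scripts/tripleland.R` wraps the pipeline for shell use
(`synth`, `run-all`, `show-config`).

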