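# spacepart

Space-partitioning analysis for group-living, non-territorial animals.

`spacepart` asks how neighbouring groups come to share — or avoid — space
when nobody defends a boundary. It was built around grid-based movement
data of mountain gorilla groups, where annual home ranges overlap heavily
but intensively used core areas are largely exclusive, and it provides the
full chain from raw field tables to that conclusion:

1. **Per-cell food availability.** Vegetation transect records plus
   per-species dry-weight calibrations and energy contents give an energy
   density (kcal m⁻²) for every 500 m grid cell; unsurveyed cells are
   masked, not zero.
2. **Movement decisions.** GPS fix tables become per-day, per-cell travel
   distances and *cell-entry decisions* — which of the up-to-8
   neighbouring cells a group entered.
3. **Previous use.** For each group, cell and date, the composite
   statistic

   PU(c, t) = Σ over earlier visits i of (group size / days since visit i) × (track length in c during visit i),

   computed from a running usage ledger, for the group itself and for all
   neighbouring groups collectively.
4. **Choice model.** A conditional logit on the choice sets:
   P(cell k entered) = exp(xₖβ)/Σⱼ exp(xⱼβ), with log-z-transformed
   predictors (food, own previous use, neighbours' previous use) and an
   offset log(1/n candidates) that defines the uniform-choice null. The
   full–null comparison uses a weighted permutation test (edge-adjacent
   cells are more readily entered than corner-adjacent ones; the chosen
   flag is reshuffled accordingly and the model refitted).
5. **Utilization model.** A Gaussian LMM (lme4, ML) of log distance
   travelled in a chosen cell on the same predictors split into
   within-group and between-group components, with group / cell /
   group-by-cell random intercepts and a spatio-temporal autocorrelation
   term; full–null comparison by likelihood-ratio test (χ², df = 6).
6. **Annual ranges.** Fixed-bandwidth (h = 200 m) Gaussian kernel
   utilization distributions from one location per day, 90 % (home range)
   and 50 % (core area) percent-volume contours on a 50 m raster,
   per-group and pairwise overlap percentages, exclusive core areas,
   area-weighted energy densities, and subsampling sensitivity.
7. **Exact statistics.** An exact Wilcoxon signed-rank test (full
   sign-permutation distribution, midranks, zeros dropped) for paired
   per-group comparisons, plus medians/ranges and threshold counts.

A multi-group movement simulator (`sim_config()`, `simulate_movement()`)
generates landscapes and GPS tracks with *known* choice coefficients —
ten groups of 4–13 animals, ~808 m daily travel, cell energies spanning
0–13 054 kcal m⁻², configurable observation fraction — so every stage can
be validated end-to-end (decision recovery ≥ 95 %, coefficient recovery
within Monte-Carlo error).

## Worked example

Simulate ten groups for a year with food attraction, site fidelity and
neighbour avoidance, then re-estimate the generating coefficients from
the simulated GPS fixes alone:

```r
library(spacepart)

cfg <- sim_config(seed = 101, n_days = 280, observed_fraction = 1,
                  beta_food = 0.5, beta_self = 0.5, beta_nbr = -0.5)
sim <- simulate_movement(cfg)
sim
#> <sim_output> 10 groups, 280 days; 2005 true decisions (2005 observed), 96653 fixes

res <- refit_simulation(sim, n_perm = 200, seed = 1)
round(res[, c("est_food", "est_self", "est_nbr", "perm_chisq", "perm_p",
              "decision_recovery")], 3)
#>   est_food est_self est_nbr perm_chisq perm_p decision_recovery
#> 1    0.513    0.493  -0.488    1282.28  0.005                 1
```

All three coefficients come back near their true values (0.5, 0.5,
−0.5); the permutation test rejects the no-preference null (the smallest
p the add-one estimator can report at 200 permutations is 1/201 ≈ 0.005);
and >99 % of the true cell transitions were recovered from the noisy
fixes. The annual-scale summary uses the published ten-group overlap
table shipped with the package:

```r
t1 <- bwindi_overlap_table()
wilcoxon_signed_rank_exact(t1$pct_overlap_hr, t1$pct_overlap_core)
#> Exact Wilcoxon signed-rank: T+ = 55, N = 10, p = 0.001953
median_range(t1$pct_overlap_hr)
#> median    min    max
#> 42.025  9.680 94.790
median_range(t1$pct_overlap_core)
#> median    min    max
#>   4.26   0.00  76.09
count_below(t1$pct_overlap_core, 10)
#> [1] 7
```

Every group shares a larger fraction of its home range than of its core
area (all ten paired differences positive, hence T⁺ = 55 and the exact
two-sided p = 2/2¹⁰ ≈ 0.002), and seven of ten groups keep core overlap
below 10 % — the annual signature of neighbour avoidance.

`run_analysis()` orchestrates the whole pipeline from CSV inputs (fixes,
group sizes, energy field or transects, grid, burn-in date) to a report
bundle (JSON fits, overlap CSV, GeoJSON contours); a thin command-line
wrapper with verbs `simulate` / `analyze` / `study` lives at
`inst/cli/spacepart.R`.

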