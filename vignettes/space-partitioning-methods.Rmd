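---
title: "Methods: grid-based movement decisions and home-range overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based movement decisions and home-range overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacepart)
```

# The scientific problem

Non-territorial group-living animals — the motivating system is the
mountain gorilla, living in cohesive groups whose home ranges overlap
extensively — do not defend range boundaries, yet their intensively used
*core areas* can be nearly exclusive. `spacepart` implements a complete
analysis chain for asking *why*: do daily movement decisions respond to
food availability, to a group's own previous use of an area (site
fidelity), and to previous use by neighbouring groups (avoidance), and do
those decisions add up, over a year, to partitioned space?

The chain runs on a square analysis lattice (500 m cells by default,
half-open so every point belongs to exactly one cell) and has four
statistical layers, each usable on its own.

# Layer 1: from field data to per-cell quantities

**Energy density.** Vegetation transects (10 plots of 1 m² per 200 m
transect) record a size measure per food-plant species. Per-species OLS
calibrations convert the measure to dry biomass (negative predictions
clamped to zero), biomass is averaged over all of a cell's plots (a plot
where a species is absent contributes zero for that species), multiplied
by the species' energy content (kcal/g) and summed over species, giving
kcal m⁻² per cell. Cells with no plots are *masked*, not zero — absence of
data is not absence of food — and masked cells are excluded from choice
sets downstream. Plain linear calibrations are the default because the
functional forms behind published biomass regressions vary by species;
callers can fit and supply their own calibration table.

**Travel per cell.** GPS fixes are joined into daily polylines; segments
crossing a cell boundary are split at the boundary by linear
interpolation, so the per-cell distances of a day sum exactly to the
day's path length. A segment crossing several boundary lines (a corner
cut) is split at every line and each piece is assigned by its midpoint.

**Entry decisions.** A decision is a transition from the current cell
into one of its up-to-8 neighbours with food data; repeated entries of
the same (origin, chosen) pair within a day collapse to one decision
(a `chosen`-only and a no-deduplication variant are selectable).
Because metre-scale GPS noise flips single fixes across boundaries, cell
runs shorter than `min_run = 2` fixes are treated as spikes and merged
into the preceding cell before transitions are read off; the same concern
motivates the pipeline's 50 m noise floor on ledger visits (a "visit" of
a few metres to a cell is a boundary overhang of noise, and because the
previous-use predictor is log-transformed such phantom visits would
distort it badly near zero).

# Layer 2: the composite previous-use statistic

For a group $g$, cell $c$ and reference date $t$,

$$\mathrm{PU}_g(c,t) \;=\; \sum_{\text{visits } i:\, t_i < t}
\frac{\text{group size}(t_i)}{t - t_i}\,\times\, d_i ,$$

where $d_i$ is the track length of visit $i$ in the cell and $t - t_i$ is
in whole calendar days. Group size (mean weaned individuals of the
visit's month) stands for depletion pressure, the hyperbolic time decay
for vegetation regrowth, and track length for how intensively the cell
was used. Visits are aggregated to one record per (group, cell, day)
first, so $t-t_i \ge 1$ and same-day earlier passes contribute nothing.
The neighbour version sums $\mathrm{PU}_{g'}$ over all other monitored
groups collectively. Unobserved days simply contribute nothing — the
statistic deliberately underestimates on sparsely observed data — and a
configurable burn-in date excludes the ledger-poor start of a study from
analysis rows while keeping pre-burn-in visits as history.

# Layer 3: the two movement models

**Choice of the next cell.** Each decision yields a choice set: one row
per candidate cell with three predictors, each log-transformed
($\log(x+c)$ with $c$ = half the smallest positive value, so zeros stay
finite; $c=1$ if all zero) and z-scored. The model is a conditional
logit: the chosen candidate $k$ has probability
$\exp(x_k\beta)/\sum_j \exp(x_j\beta)$ within its set. This is the exact
choice-set analogue of a binomial model with an offset
$\log(1/n_{\text{candidates}})$: the offset is constant within a set and
cancels from the conditional likelihood, and the $\beta=0$ likelihood is
exactly $\sum_i \log(1/n_i)$ (uniform choice). We use the conditional
likelihood rather than a binomial GLMM with choice-set random intercepts
because it conditions on the one-chosen-per-set structure exactly,
needs no random-effect machinery, and pairs naturally with permutation
inference; per-group random slopes are a known limitation, not
implemented.

The full-null test is a *weighted permutation*: the observed statistic is
the deviance $2(LL_{\text{full}} - LL_{\text{null}})$; each permutation
reassigns every set's chosen flag to one candidate drawn with weights
reflecting that edge-adjacent cells are entered more readily than
corner-adjacent ones (a path into a corner neighbour must pass through a
single point), then refits. Weights default to the empirically observed
per-candidate choice rates of the two adjacency classes, renormalized
within each set, and can be overridden. The p-value uses the add-one
estimator $(1 + \#\{S_{\text{perm}} \ge S_{\text{obs}}\})/(1 + n_{\text{perm}})$,
with $n_{\text{perm}} = 1000$ by default.

**Utilization of a chosen cell.** The response is log distance travelled
in a visited cell that day (zero-distance rows carry no utilization
signal and are dropped). Each transformed predictor is split into its
group mean (*between*-groups part) and the deviation from it
(*within*-groups part), because "groups that sit on rich ranges travel
differently" and "a group travels differently when it is in a rich cell"
are different effects; the parts always reconstruct the original
exactly. The model is a Gaussian linear mixed model (fitted by ML via
`lme4`) with random intercepts for group, cell and group-by-cell, plus an
autocorrelation covariate: for each row, the Gaussian-kernel-weighted
mean of the other same-group residuals from a fit without the term,

$$w = \exp\!\left(-\tfrac{\Delta t^2}{2\sigma_t^2}\right)
      \exp\!\left(-\tfrac{\Delta s^2}{2\sigma_s^2}\right),$$

with $\Delta t$ in days and $\Delta s$ the distance between cell centres.
$(\sigma_t, \sigma_s)$ are chosen by profile likelihood over a small grid
(defaults $\sigma_t \in \{1,3,7,14,30\}$ d, $\sigma_s \in \{250,500,1000,2000\}$ m);
simulation studies fix them at (7 d, 1000 m) to avoid a grid search per
replicate. Weighting only same-group residuals is a choice — residual
dependence here is dominated by a group revisiting its own recent
locations — and is exposed in the function interface. The full-null
comparison drops the six predictor terms, keeps the random effects and
the autocorrelation term, and refers $2\Delta LL$ to $\chi^2_6$; this is
a fixed-effects test with identical random structure under both models,
where the boundary problems of variance-component LRTs do not arise.
One caveat matters in practice: three of the six tested terms are
group-level (between) predictors, so their effective sample size is the
number of groups. With ten groups the $\chi^2_6$ reference is
optimistic — in the package's own null simulations the nominal 5% test
rejects 12–15% of the time — while with thirty or more groups it
calibrates (4–5%). The test suite records both facts; small-sample
inference on between-group terms should be treated as approximate (a
parametric bootstrap of the LRT would be the remedy when group counts
are small).

# Layer 4: annual ranges and overlap

Home ranges use fixed-bandwidth ($h = 200$ m) bivariate Gaussian kernel
density estimation on one location per day (the first fix — appropriate
when daily travel, around 808 m, is small relative to the range), on a
raster of 50 m pixels over the points' bounding box padded by $4h$. The
90% (home range) and 50% (core area) percent-volume contours select
pixels in decreasing mass order until the level is reached; regions are
unions of pixels, deliberately unsmoothed so that areas and overlaps are
exactly reproducible set operations. Halving the pixel size changes the
closed-form test areas by well under 2%, which is why 50 m is the
default. For overlap, all groups' distributions are built on one common
extent; per group $i$, the shared fraction is
$100\,\cdot\,\mathrm{area}(P_i \cap \bigcup_{j \ne i} P_j)/\mathrm{area}(P_i)$,
the exclusive core is the unshared remainder, and a pairwise matrix is
attached (shared areas are symmetric; percentages are not). Energy
density of a region is the cell-area-weighted mean over the region's
pixels, with masked cells excluded from numerator and denominator.

Comparisons of paired per-group quantities (home-range vs core overlap
percentage; core vs rest-of-range energy density) use an exact Wilcoxon
signed-rank test: zeros dropped, midranks for ties, the null distribution
of $T^+$ built by convolution over doubled ranks (equivalent to full
$2^n$ sign enumeration), and a two-sided p that doubles the smaller tail
and caps at 1 — the convention of the classical exact-rank
implementations. For the published ten-group overlap table this gives
$T^+ = 55$, $p = 2/1024 \approx 0.002$.

# The synthetic-data generator

`simulate_movement()` is a first-class module, not a fixture: it
generates data from the *same* model family the estimators assume, so
every pipeline stage can be validated end-to-end with known truth.

* The landscape is smoothed white noise rescaled to
  $[0, 13054]$ kcal m⁻², matching the span observed in the motivating
  field system; ten groups of 4–13 individuals, ~50% of days observed,
  and a mean daily travel of 808 m are likewise the default conditions.
* Each simulated day draws a lognormal target length; the group wanders
  inside its current cell and, while length remains, steps to a
  neighbour drawn with probability
  $\propto \exp(\beta_f z_f + \beta_s z_s + \beta_n z_n)$, with
  previous-use values computed from the running ledger by the same code
  the analysis uses. Within-cell wander length is lognormal with
  configurable loadings on the same z-scores (default: a negative
  neighbour loading), which is the generative mirror of the utilization
  model. The day stops when the remaining budget falls below a typical
  crossing cost (a fixed 350 m); any unspent remainder is walked out in
  place. The stop rule deliberately never looks at the drawn candidate:
  a budget check on the chosen cell's actual crossing cost would
  selectively discard expensive moves and bias the realized choice
  process away from the model being simulated.
* Rook transitions cross the shared edge midpoint and diagonal
  transitions cross exactly through the shared corner, so the declared
  cell sequence is geometrically consistent with the fixes; fixes are
  interpolated at 25 m spacing with 5 m Gaussian jitter.
* Simulation operates on the z-scale directly: the fixed transform
  states for previous use (shift 1, mean 2, sd 2) and the food state
  fitted to the landscape are exported with the truth record, so refits
  can share the generating parameterization exactly.

What the generator does *not* emulate: topography, vegetation phenology,
demography and group fissions, female transfers, observer-driven
missingness patterns, and autocorrelated GPS error. Passing tests
therefore demonstrate correctness of the estimators under the assumed
model, robustness to independent GPS noise and day thinning — not
robustness to every feature of real field data.

`simulate_choice_sets()` and `simulate_utilization_rows()` generate
choice sets and utilization rows directly on the z-scale, bypassing
movement; they exist because calibration studies (type-I error over
hundreds of replicates) need thousands of model fits, and they simulate
exactly the null (or alternative) the tests assume.

# Numerical and design choices

* **Conditional-logit fitting** is Newton–Raphson on the analytic score
  and information; complete separation is flagged as non-convergence
  (|β| > 15 or a singular information matrix). The fit is cross-checked
  in the test suite against an independent grid-search oracle and
  against `survival::clogit`.
* **Degenerate inputs:** single-candidate choice sets are dropped;
  single-fix days yield one zero-distance visit; a single observation in
  a group gets autocorrelation term 0; all-zero predictors error at the
  z-step (zero variance).
* **Dates** are whole calendar days; fixes with duplicated timestamps
  keep the first record with a warning.
* **Determinism:** every stochastic function takes an explicit seed and
  restores the caller's RNG state, so a config plus seed reproduces a
  report byte for byte.
* **Problem sizes in the validation suite** were chosen to exercise the
  asymptotics that matter while staying lightweight: type-I error of the
  permutation test uses 200 replicates × 200 permutations × 500 sets;
  the utilization LRT calibration uses 200 replicates of 400 rows from
  10 groups; end-to-end coefficient recovery uses one 220-day,
  ten-group simulation (~1600 decision sets) with fully observed days.
  Full observation is deliberate there: 50% day thinning biases the
  reconstructed usage ledger downward (acknowledged underestimation, not
  an estimator defect), so estimator consistency is tested where the
  measurement model is complete, and thinning effects are exercised
  separately and qualitatively.

# Known limitations

* No random slopes in either model; the utilization model's
  random-intercept structure is a simplification of what a full
  random-slopes specification would carry.
* The choice model has no group-level heterogeneity in β.
* Percent-volume contours are pixel unions; areas are reported to the
  pixel resolution, and agreement with smoothing-based home-range
  software is approximate by design.
* The previous-use ledger sees only observed days; with heavy thinning
  its values (and hence fitted self/neighbour effects) are attenuated.
* Planar metric coordinates are assumed throughout; no CRS handling.
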