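---
title: "Methods: additive-benefit ranking and range-size-dependent gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive-benefit ranking and range-size-dependent gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scprank)
```

`scprank` ranks every cell of a gridded landscape by its marginal value for
a pool of species, forces existing protected areas (PAs) to the top of the
ranking, cuts the ranking at land-coverage targets, and scores each
scenario with a range-size-dependent representativeness criterion. This
vignette is the package's own account of the model, its conventions, and
the design decisions taken where the method family (Zonation-style
cell-removal prioritization) leaves choices open.

## 1. The cell-removal model

The landscape is a lattice of cells (class `scp_grid`): dimensions, a
per-cell area in km² (default 1, the common national-scale convention),
and a validity mask. All layers — binary species ranges, cost, PA mask,
ranks — live on one shared grid; nothing is resampled implicitly.

Ranking proceeds by *removal*: starting from the full landscape, the cells
least worth keeping are discarded first, and the removal position (divided
by the number of valid cells) is the cell's priority rank in (0, 1]. The
value of keeping cell $i$ is the additive benefit function (ABF) marginal

$$\delta_i \;=\; \frac{1}{c_i}\sum_j w_j\,\bigl[V(q_j) - V(q_{j,-i})\bigr]
\;+\; \beta\,\Delta\!\left(\frac{BL}{A}\right),$$

with $q_j$ the fraction of species $j$'s total occurrence still remaining,
$q_{j,-i}$ the same quantity after hypothetically removing cell $i$,
$w_j$ the species weight, $c_i$ the cell cost, and
$\Delta(BL/A)$ the post-minus-pre change of the boundary-length-to-area
ratio of the remaining patches.

**Benefit function.** The ABF family needs a concrete $V$; the method
literature does not fix one, so `scprank` uses $V(q) = q^z$ with default
$z = 0.25$, the conventional ABF curvature: strongly concave, so losing
the first cells of a well-represented species costs little while the last
cells of a depleted range are nearly irreplaceable. $z = 1$ (linear
benefit) is available and is what the hand-checkable unit examples use.
The exponent is recorded in every run manifest; results are a function of
the declared $z$, not a reproduction claim about any specific software's
internals.

**Sign convention for the penalty.** $\Delta(BL/A)$ is *after minus
before*. Removing a cell whose loss would make the remaining patches less
compact (ratio rises) therefore *raises* $\delta_i$ and defers that
removal. This is the only orientation under which a larger $\beta$ yields
more compact retained sets, which is the defining property of a boundary
length penalty; the package's compactness property test checks exactly
that direction.

**Weights and costs.** Weights default to the IUCN Red List mapping LC 1,
NT 2, VU 3, EN 4, CR 5 (unknown categories are an error, never a silent
1). Costs default to 10 on natural land-cover classes and 1 on
human-associated classes — an acquisition-cost proxy in which
already-transformed land is an order of magnitude cheaper to place under
protection.

## 2. The ranking loop and its numerics

Per iteration: candidates are computed, $\delta_i$ is evaluated once for
all of them, the `warp` lowest-valued candidates are removed *as a batch*
(no intra-batch recomputation), and state updates once. Defaults:
$\beta = 0.1$, `warp = 50`.

* **Edge removal** (default on): candidates are remaining, unprotected
  cells with at least one non-remaining neighbour under the configured
  4- or 8-neighbourhood, or on the lattice border; NoData counts as
  non-remaining. If unprotected cells remain but none is on an edge
  (possible when a PA ring encloses them), all remaining unprotected cells
  become candidates rather than stalling.
* **Boundary length** is always counted in 4-neighbour cell *sides*,
  whatever the candidate neighbourhood, and $BL$ and $A$ are totals over
  all remaining patches (one global ratio). Removing a cell with $k$
  remaining 4-neighbours updates $BL' = BL - 4 + 2k$ in O(1); the exported
  `boundary_delta()` instead recounts from scratch and doubles as the
  independent check of that update.
* **Ties.** Equal $\delta_i$ are ordered by a random permutation drawn
  once from the configuration seed, then by linear cell index — reproducible
  but without systematic spatial bias. (R matrices are column-major, so
  the final deterministic key is the column-major linear index; any fixed
  total order serves, and the convention is recorded here and in the
  manifest.)
* **Forced PA inclusion.** PA cells are never candidates. When only PA
  cells remain, they are removed one at a time (warp 1) by the same
  $\delta_i$ rule evaluated on the PA-only landscape, giving them the
  highest ranks in a deterministic internal order.
* **Exactness.** For binary layers all representation numerators are
  integer-valued doubles, and $q_{j,-i}$ is computed as
  $(r_j - o_{ij})/t_j$ — numerator subtracted *before* the division — so
  the incremental path agrees *bit for bit* with the from-scratch oracle
  (`greedy_oracle()`), and the equivalence test can demand identity rather
  than tolerance.

Degenerate inputs: a species with zero total occurrence is an error naming
the species; a PA mask covering everything yields all ranks from the
PA-phase ordering with a warning; the $\beta$ term is skipped when a
removal would empty the landscape (ratio undefined).

## 3. Range mapping conventions

**Binarization.** The threshold is the 10th percentile (configurable) of
suitability at the training presences; cells at or above it form the
binary range. Percentile definition: linear interpolation of the
*empirical CDF* between order statistics (R `quantile` type 4). The choice
matters: the more common type-7 interpolation can strand
$\lfloor(n-1)p\rfloor + 1$ presences below the threshold — 3 of 25 = 12%
for $p = 0.1$ — violating the defining property of the "10th percentile
training presence" rule, that at most 10% of training presences fall below
the cutoff. Type 4 guarantees the strictly-below count is at most
$\lfloor np \rfloor$. The convention is recorded in layer metadata and the
run manifest. `percentile = 0` reduces to the minimum-training-presence
threshold.

**Breadth classes.** Range sizes below 1,000 km² are *restricted*, above
25,000 km² *wide*; the boundaries themselves (stated as strict
inequalities, hence open) are assigned to *intermediate*.

**Evaluation.** AUC is the rank-based (Mann–Whitney) presence-background
statistic with half-credit ties, hence invariant under any strictly
increasing rescoring; TSS is sensitivity + specificity − 1, thresholded at
the same binarization threshold (the method family does not name a
separate TSS threshold). The default background is all valid cells; a
target-group background can be supplied. Spatial-block cross-validation
tiles the grid into square blocks dealt randomly and evenly to $k$ folds
(default 5), with all records of a block sharing a fold. Because no niche
model is fitted inside the package, evaluation applies to *supplied*
suitability surfaces; no comparison with any published fold-averaged AUC
is meaningful.

**Collinearity.** `collinearity_filter()` visits variables in a
caller-supplied relevance order and keeps a variable iff |Spearman ρ| <
0.7 against everything already kept — the standard greedy pruning of
highly correlated predictors, applied to a precomputed matrix.

## 4. The well-represented criterion

Coverage is $100\,|range \cap mask| / |range|$ on the shared grid (no
partial-cell weighting). The requirement is 100% below 1,000 km², 10%
above 25,000 km², and between the breakpoints

$$\mathrm{required}(a) = 100 - 90\,\frac{a - 1000}{25000 - 1000},$$

linear in *raw area*. Whether the interpolation should run in raw or log
area is genuinely underdetermined ("based on the range size" admits both);
linear-in-area is the plain reading and the default, and a `"log-area"`
switch (same endpoints, linear in $\log a$) is provided for sensitivity
analysis rather than guessed at. Both variants are continuous and
non-increasing; boundary areas take the interpolated endpoint values
(100 and 10), keeping the function continuous where the strict
inequalities left the boundary open.

## 5. Scenarios

`select_top_fraction()` takes the `round(f·N)` highest-ranked cells
(round half away from zero — immaterial at national scale, but toy grids
need a fixed rule). Forced PA inclusion makes every scenario a superset of
the PA mask, and top-fraction selections of one ranking are nested.
`expansion_summary()` reports, for land fraction, mean coverage and count
of well-represented species, the relative increase $100(b-a)/a$ and the
fold ratio $b/a$; these conventions reproduce the in-print arithmetic
(6.12 → 11.89 is +94.28%; 5 → 30 is 6-fold). A zero baseline yields an
`NA` marker, not an error.

## 6. The virtual-landscape generator

The simulator produces inputs with the statistical structure the analysis
assumes; its defaults state that world once:

* **Land cover**: a Voronoi mosaic over randomly seeded patches
  (`patchiness` ≈ patch diameter in cells, default 5); seed classes are
  drawn so the expected cell fraction in natural classes equals
  `natural_fraction`. Natural codes come first; the class table drives the
  10-vs-1 cost layer.
* **Suitability**: isotropic Gaussian kernel (sd `spread`, in cells) times
  land-class affinity, times a truncated noise factor
  $\max(1 + e, 0)$, $e \sim N(0, \texttt{noise\_sd})$, clipped to [0, 1].
  The noise is *signal-modulated* rather than added globally: additive
  zero-mean noise has total mass proportional to grid size and swamps the
  kernel of a restricted species (on a 200×200 grid a spread-1.5 species
  binarizes to ~13,000 km² of pure noise), defeating the design goal that
  one parameter (`spread`) controls realized range size, and breaking the
  hard-mask property that a zero-affinity class has exactly zero
  suitability. Multiplicative noise preserves both.
* **Presences**: sampled with replacement, probability ∝ suitability —
  presence-only records where hotspots are resampled. Pool defaults:
  spreads log-uniform over [1.5, 40] cells (range sizes spanning orders of
  magnitude, restricted through wide), 21–200 records per species
  (mirroring the >20-record modelling floor), IUCN categories drawn
  LC-heavy (60/15/10/10/5%), matching the skew of assessed faunas.
* **Protected areas**: `n_patches` compact 4-connected patches grown by
  seeded region-growing to exactly `round(fraction · n_valid)` cells
  (default fraction 0.05, the ~5%-of-land baseline) — compact like real
  reserves, which exercises the edge-removal logic.
* **Determinism**: every generator takes one explicit integer seed and
  restores the caller's RNG state; identical arguments give bit-identical
  layers.

What the simulator does *not* emulate: real spatial autocorrelation
structure of climate, species' aggregation beyond a unimodal kernel,
coastline/NoData geometry, or observation bias in records. A green test on
synthetic data therefore establishes the correctness of the *algorithms
and contracts*, not calibration to any real region; the spatial statistics
of the patches are a modelling choice, not fitted to data.

## 7. I/O and reproducibility

Rasters are plain-text ESRI ASCII grids written with 17 significant
digits, so write→read round-trips doubles bit-exactly; GeoTIFF is
deliberately out of scope in this build (no raster dependency), and `.tif`
paths raise a format error rather than mis-reading. On-disk occurrence
CSVs use 0-based row-major indices with the origin at the top-left cell;
in-memory sets are 1-based R conventions. `run_pipeline()` writes a JSON
manifest with the full configuration, every declared convention
(percentile method, $z$, interpolation mode, neighbourhood, tie-break,
rounding), per-stage timings and an MD5 checksum of every output file;
rerunning the manifest's configuration reproduces every file checksum.

## 8. Known limitations

* The exact benefit function and penalty numerics of any particular
  prioritization software are not reproduced; $z$ and the sign convention
  are declared parameters of *this* implementation.
* Performance-curve resolution is bounded by `warp`: within a removal
  batch, cells are ordered by the start-of-iteration $\delta_i$.
* `greedy_oracle()` is $O(\text{cells}^2 \cdot \text{species})$ per run
  and intended for ≤ ~12×12 validation instances only.
* Coverage is cell-counting; no area-weighted partial overlap, no
  uncertainty propagation from suitability error into coverage.
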