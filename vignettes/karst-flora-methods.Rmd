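---
title: "Methods: gridded richness, species-area nulls and endemism for karst floras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded richness, species-area nulls and endemism for karst floras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karstflora)
```

## What the pipeline estimates

`karstflora` asks, for a set of karst polygons embedded in a larger study
area, whether the karst flora is unusually species-rich or unusually rich in
range-restricted (endemic) species, and how much it contributes to the
regional species pool and to the pool of threatened species. The analysis
operates on georeferenced herbarium occurrence records and proceeds through
fixed stages: coordinate cleaning and name reconciliation, equal-area
gridding at 50 km (with 10 km subcells), per-cell richness with a bootstrap
species-area null, weighted endemism with a randomization null,
range-size and small-range statistics, keyword-based validation of the
karst map against collection-label metadata, and an IUCN cross-tabulation.

Because the occurrence archives, karst maps and red lists this kind of
study consumes are large external resources, the package ships a
synthetic-data module that generates inputs with the statistical structure
the analysis assumes. Every stage is exercised end to end on that
synthetic landscape; the published count tables of the motivating study
are shipped as plain CSV fixtures so their percentage arithmetic can be
recomputed and machine-checked.

## The synthetic landscape

`landscape_spec()` fixes the study conditions; its defaults are the
conditions under which the test suite and the acceptance script run:

* **Coordinate error.** Half of the records (`coord_error_fraction = 0.5`)
  carry a declared uncertainty of 5,000 m and a positional jitter of at
  most 5 km, mirroring the coordinate quality reported for the occurrence
  archive the study used. This is also why a 5 km buffer (`BZ5`) of the
  karst extent (`NBZ`) is analysed alongside it.
* **Karst cover.** `karst_fraction = 0.05`, inside the 3.7-6.3% band the
  study reports for Brazil. The generator places disjoint random convex
  blobs and rescales the closing blob so the realized fraction hits the
  target exactly.
* **Range structure.** Species ranges are discs. A `single_cell_fraction`
  (default 0.29, the study-area share of single-cell species) of the pool
  receives a small radius (1-20 km) and a centre placed so the disc fits
  inside one 50 km cell; the remainder receive radii of 25 km plus an
  exponential tail (mean 40 km), which cannot fit a single cell. The
  resulting occupied-cell distribution is reversed-J. Disc ranges are a
  deliberate simplification: the source study never states true range
  geometry, and discs suffice to induce the cell-count distribution the
  analysis depends on.
* **Collection effort.** Sampling is thinned by a mixture of Gaussian
  bumps (sd 40 km) at fifteen random "herbarium towns"; `effort_bias`
  scales bump height, with 0 giving uniform sampling. No quantitative
  description of the real archive's spatial bias exists, so this surface
  is a stand-in chosen to produce the clustered collection densities such
  archives show, not an estimate.
* **Names and categories.** A permissive backbone accepts every name; a
  stricter one treats `synonym_fraction` (default 0.166, the published
  strict-checklist synonym rate) of names as one-hop synonyms and a
  further fixed 5% as not found. Red-list categories are assigned
  independently with probabilities scaled from the published country-level
  table (most species unevaluated).
* **Scale.** 400 species and 18,000 records on a 600 x 600 km landscape
  (45 records per species, close to the study's 44). These sizes keep a
  full pipeline run with 1,000 bootstrap draws and 2,000 randomization
  draws in the tens of seconds while leaving every statistic well away
  from degenerate regimes.

All randomness flows from one integer seed through a derived stream per
sub-generator (`derive_seed()`), so any stage can be regenerated
independently and a fixed seed yields bit-identical outputs.

What the generator does **not** emulate: phytogeographic domains, climate,
spatial autocorrelation of species composition beyond disc ranges, and
real taxonomic noise (misidentifications, fuzzy name variants). Passing
tests therefore certify the arithmetic and the statistical machinery, not
the ecological fidelity of any particular real dataset.

## Geometry and gridding

All analysis happens in projected kilometre space. Synthetic landscapes
are generated directly in planar km (a passthrough projection); real
degree data can be projected with the spherical Albers equal-area conic
(defaults: central meridian -60°, standard parallels -5° and -42°,
latitude of origin -32° — the standard South America parameterization;
the projection is named but not parameterized in the source study, so the
parameters are configurable). The projection round-trips to 1e-6 degrees
and preserves area to well under 0.5% across the domain.

Grid cells are half-open, `[x0 + i*s, x0 + (i+1)*s)`, zero-based
`(col, row)`, so every point belongs to exactly one cell and boundary
points go to the higher-index cell — this prevents double counting.
The grid origin is the projected bounding-box minimum floored to the
nearest cell multiple, making indices reproducible; anchoring to a
national extent instead would shift memberships near edges, which is why
the anchor is part of the grid object.

Polygon primitives (shoelace areas, ray-cast membership, convex-polygon
buffering, convex clipping, point-polygon distance) are implemented in
the package. Buffered areas of convex polygons use the exact closed form
`A + P*r + pi*r^2`; the discretized arc boundary (1,024 segments per full
circle) is used only for membership and distance tests. Unions fall back
to pairwise inclusion-exclusion, and to a fine-grid count (0.25 km
resolution) only when triple overlaps are possible. The study area is the
axis-aligned bounding box of the buffered karst extent, so the nesting
`NBZ ⊆ BZ5 ⊆ study area` holds for every derived statistic.

## Cleaning and reconciliation

`clean_coordinates()` applies six switchable steps in fixed order:
missing/zero coordinates, out-of-range coordinates, `lat == lon`, country
mismatch, off-land, and proximity (default 10 km) to a country centroid.
This is a reconstruction of the standard occurrence-cleaning suite; the
report names each step so the mapping to any particular tool's argument
set is auditable, and the bookkeeping identity
`input = retained + sum(removed)` is enforced. Duplicates are retained:
richness counting is idempotent to them, and dropping them is a policy
decision the pipeline deliberately does not take.

Name matching is exact on the whitespace-normalized binomial after
one-hop synonym flattening; no fuzzy matching, mirroring lookup-service
behaviour. Unresolvable records are preserved on an unresolved list
rather than silently dropped. `backbone_congruence()` reports shared /
synonymous / not-found counts with percentages to one decimal,
**half-up** rounded (`pct_of()`), the convention that reproduces the
published tables.

## Richness and the species-area null

Per-cell richness is the count of distinct accepted names; the
effort check is an OLS of `sqrt(S)` on `sqrt(record count)`.

The richness null for an extent works on the records inside it:

1. resample the records with replacement at full size (1,000 draws);
2. per draw, build the 10 km-cell species-accumulation curve and fit the
   Arrhenius power law `S = k * A^z` (nonlinear least squares on the raw
   scale, initialized from the log-log regression, with a
   Levenberg-Marquardt fallback; flat curves short-circuit to the exact
   degenerate fit `k = S, z = 0`);
3. per draw, give each 50 km cell an expected richness `k * A^z` with `A`
   its number of occupied 10 km subcells;
4. classify each cell's observed richness against the 25th/75th type-7
   quantiles of its 1,000 expected values: strictly below → -1, strictly
   above → 2, else 1.

Two readings were open. "Random draws of occurrence data" is read as a
bootstrap of records (not cells) at full size — the draw size is not
stated in the source, so it is recorded in the run metadata and a switch
(`occupancy = "draw"/"observed"`) controls whether `A` is recomputed per
draw (default: each draw is a complete re-analysis of a resampled
dataset) or held at its observed value (under which the null collapses to
parameter uncertainty only and has essentially zero width).

Inside the null, the accumulation curve is evaluated as the closed-form
expectation of the random-accumulation process,
`E[S(n)] = sum_s (1 - C(N - m_s, n)/C(N, n))`, at 25 thinned sizes - this
is the infinite-permutation limit of the permutation curve and is
cross-checked against `vegan::specaccum(method = "exact")` in the tests.
The standalone `accumulation_curve()` delegates to `vegan::specaccum`
(permutation method by default, 100 permutations, seeded).

**Known limitation.** The spread of the 1,000 per-draw predictions
`k * A^z` is a confidence band for the *mean* richness at a given
occupancy, not a prediction band for a single cell's observed richness;
and a global power-law fit to a saturating curve is biased at the small-A
end. Consequently, on exchangeable synthetic data the outlier classes do
not land at 25/50/25 - most cells classify as outliers, exactly as the
motivating study observed on real data (a preponderance of lower
outliers, interpreted there as under-sampling). The quantile classifier
itself is calibrated: when each cell's null values are genuinely drawn
from the cell's own sampling distribution, classes occur at 25/50/25
within Monte-Carlo error, and the acceptance suite verifies precisely
that property. Interpreting pipeline outlier maps therefore requires the
same caution the original analysis required.

## The resampling extent comparison

`resample_extent_test()` draws 1,000 samples of study-area cells, each of
the karst cell count (without replacement within a sample), computes each
sample's mean statistic, and performs the one-sample two-sided t-test of
those means against the observed karst value — degrees of freedom 999,
matching the construction whose reported statistics anchor this design
(the alternative reading, a test within each sample, is inconsistent with
df = 999 and was rejected). Under exchangeability this t statistic scales
with `sqrt(n_samples)`: it measures how many standard errors *of the
replicate-mean distribution's mean* the observed value sits away, so its
parametric p is strongly anti-conservative as a hypothesis test. The
function therefore also reports an empirical randomization p (two-sided
proportion of replicate means at least as extreme), which is calibrated —
type-I error 5% at alpha = 0.05 — and is the p the pipeline reports
alongside t. The same machinery serves the small-range-species
comparison through `resample_cells_test()`, whose per-sample statistic is
the proportion of species in the sampled cells that are single-cell on
study-area ranges. The small-range distributions can be bimodal on real
data; the t-test is reported regardless, as in the source analysis, and
no correction is applied.

## Endemism

Range size `r` is the number of occupied 50 km cells within a named
extent ("cell-based", Area-of-Occupancy-like). Weighted endemism is
`WE(cell) = sum over species present of 1/r`; corrected weighted endemism
is `CWE = WE / S`. Both range bases are computed side by side —
extent-restricted (which overestimates endemism for species whose ranges
extend beyond the extent) and study-area-wide (the conservative
measure) — because the contrast between them is itself a result.
`sum over cells of WE` equals the species total exactly, a conservation
law the tests enforce on random layouts.

The endemism null draws, for each cell of observed richness `S`, 2,000
samples of `S` species from the pool without replacement within a draw (a
cell cannot contain a species twice) and flags the observed WE outside
the two-tailed type-7 empirical quantiles at `alpha = 0.05` (threshold
configurable; the source states only that significance was estimated).
At heavily reduced draw counts the strict exceedance of an interpolated
empirical quantile is biased upward (about 5.9% at 200 draws) — a
property of the quantile estimator, which is why the default stays at
2,000 draws.

## Karst-map validation

Habitat notes are tokenized after lower-casing and accent folding, so
'calcário' and 'calcario' match either spelling; matching is on whole
tokens to avoid false hits of short keywords inside other words (the
source is silent on this; substring matching would over-match terms like
'cave'). Keywords carry one of three classes: carbonate terms are
unconditional evidence; doline terms require the record to fall inside a
mapped karst polygon (automating a manual substrate check — flagged AUTO
in the report so a human can re-review); cave terms require projected
distance of at most 1 km from a carbonate record or mapped karst, since
caves occur in other lithologies. A record matching several keywords is
classed by the strongest evidence (carbonate > doline > cave). Distances
are planar in the equal-area projection; at the 1 km scale the projection
error is negligible. The anchor set is computed before the conditional
rules, so the filter is order-independent, and every excluded record
carries the rule that excluded it. `overlay_congruence()` reports the
retained records' agreement with the map and lists records beyond a
threshold (default 5 km) as candidate undocumented outcrops.

## Conservation cross-tabulation

`iucn_crosstab()` counts evaluated species per category and extent with
percentages of the country-total column, half-up rounded to one decimal.
"Conservation concern" includes NT by default — the published table's own
roll-up arithmetic (533 = 5 + 2 + 55 + 157 + 271 + 43) requires it even
though the accompanying prose lists only EX-VU — with
`concern_includes_nt = FALSE` available for the narrower roll-up.

## Orchestration and reproducibility

Stages communicate only via files (CSV/GeoJSON) under the output
directory, never in-memory, so any stage can be rerun or swapped; each
stage writes a manifest (stage, seed, parameters, input MD5 hashes)
sufficient to re-execute it bit-identically, and the resolved
configuration is written beside the outputs. The numbered scripts under
`analysis/` are thin narrative drivers over `run_stage()`; `run_all()`
runs the whole pipeline and `dry_run = TRUE` prints the plan without
writing.

## Numerical choices, in one place

* Quantiles: type 7 (linear interpolation) throughout; outlier and
  significance boundaries use strict inequalities, so ties are
  non-outliers / non-significant.
* Percentages: half-up rounding to one decimal (`pct_of()`).
* Arrhenius fit: `nls` (port algorithm, `k` bounded positive) with
  log-log initialization and `minpack.lm::nlsLM` fallback;
  non-convergence raises a typed error carrying the start values; inside
  the bootstrap, failed draws are dropped and counted, with a warning
  above 5%.
* Buffering: exact closed-form areas for convex polygons; 1,024-segment
  arcs for boundaries; buffered polygons that merge are kept as an
  overlapping set with union semantics (membership = any polygon).
* Degenerate inputs: single-species extents yield the exact flat fit
  (expected richness 1 everywhere); empty extents and empty categories
  yield zero rows, not errors, except where the contract demands an error
  (empty name lists, empty retained sets).
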