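---
title: "Coverage and sampling-effectiveness indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage and sampling-effectiveness indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssii)
```

## The problem

Occurrence records — dated, georeferenced observations of species — accumulate
at enormous rates, but raw record counts say little about how much of our
*knowledge* of species distributions is actually improving. A million records
of common garden birds near cities adds almost nothing about where most
species occur. This package quantifies two distinct aspects of that problem
on an equal-area grid:

* **Coverage** (SSII, Species Status Information Index): of the grid cells a
  species is *expected* to occupy, what fraction has at least one record in a
  given year? For species $k$ with expected range cells $N_k$ and cells with
  data $n_{k,t}$ in year $t$,
  $$\mathrm{SSII}_{k,t} = \frac{n_{k,t}}{N_k} \in [0, 1].$$
* **Sampling effectiveness** (SSEI, Species Sampling Effectiveness Index):
  given the records that were collected, how evenly are they spread across
  the sampled cells? With per-cell counts $r_i$, $R = \sum_i r_i$,
  $p_i = r_i / R$ over the $n$ sampled cells,
  $$H = -\sum_i p_i \ln p_i, \qquad \mathrm{SSEI} = \frac{H}{\ln n}.$$
  This is the familiar normalized Shannon entropy (the same construction as
  Pielou's evenness): 1 for perfectly uniform sampling, small for records
  piled into few cells, and invariant to scaling all counts by a constant.

A third ingredient connects species to nations. The **national stewardship**
$s_{k,c}$ of country $c$ for species $k$ is the fraction of the species'
global expected range falling inside the country (1 for an endemic).
National indices restrict the expected range to the country's cells;
**Steward's SSII** multiplies national coverage by stewardship, so that, per
species and year,
$$\sum_c s_{k,c}\,\mathrm{SSII}^{(c)}_{k,t} = \mathrm{SSII}^{\mathrm{global}}_{k,t}$$
holds *exactly* — national contributions are an additive decomposition of
global coverage. National aggregates for a taxonomic group are the
unweighted mean of national coverages across all expected species (National
SSII) and the stewardship-weighted mean $\sum_k s_k c_k / \sum_k s_k$
(Steward's national SSII).

## The grid and its conventions

All layers — ranges, countries, records — are indexed on one square-celled
grid in a cylindrical equal-area projection (Behrmann, standard parallel
30°, by default; the projection is a configuration field because published
grids rarely state theirs). Cell identifiers are row-major integers from 0.
Conventions that matter:

* **Half-open cells.** A cell owns its lower edges: the intervals
  $[x_{low}, x_{high}) \times [y_{low}, y_{high})$ partition the plane, so
  every point belongs to exactly one cell and boundary points are assigned
  deterministically.
* **Partial edge cells are kept** when an extent does not divide evenly
  (column/row counts round up).
* **Resolution nesting.** Halving the cell edge with the same origin splits
  every cell into exactly 4 children, and gridded record totals are
  conserved — multi-resolution analyses (e.g. 110/55/27.5 km) stay
  comparable.
* **Rejected, never dropped.** Records with invalid coordinates, an
  unparseable year, a missing species, or a location off the grid are
  counted per reason in a rejection summary.
* **Countries are exclusive** by default: each cell goes to the country with
  the largest overlapped area, ties to the lexicographically smallest ISO3
  code, because stewardship weights should sum to exactly 1 per species. A
  fractional-overlap table is available but feeds nothing downstream.
  Range cells under no country are carried as an `UNASSIGNED`
  pseudo-country, which keeps the stewardship decomposition exact rather
  than silently leaking coverage.

Polygon inputs (toy geometries, GeoJSON or coordinate rings) are rasterized
by exact rectangle clipping with three rules: any-overlap, center-in, and
majority-area. There is no geodesic-area refinement beyond the projection
itself, and no support for rings with holes.

## Parameters and conventions that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cell_size_km` | 110 | cell edge length; 55 and 27.5 give nested refinements |
| SSEI denominator | `ln(n_sampled)` | evenness over the *sampled* portion of the range; `ln(n_expected)` available |
| SSEI at 1 sampled cell | missing (`NA`) | 0/0 in the normalization; configurable to 0 or 1 |
| trend window | 2010–2019 | the "previous decade" |
| trend test | OLS slope, two-sided *t* | Mann–Kendall/Theil–Sen available |
| `alpha` | 0.01 | significance for trend classes |

Two of these deserve their rationale spelled out.

**The SSEI denominator.** Normalizing by $\ln n_{\text{sampled}}$ makes SSEI
a pure evenness measure, complementary to SSII: SSII says how *much* of the
range has data, SSEI how *well-distributed* the collected records are over
the part that does. Normalizing by $\ln N_{\text{expected}}$ instead folds
coverage back into the index (unsampled cells count as maximally uneven),
which double-counts what SSII already measures — so it is an option, not the
default.

**Missing vs zero.** A species sampled in one cell has no defined evenness
(the normalizer $\ln 1 = 0$). Returning `NA` and excluding such species from
national means is the default; substituting 0 ("one cell is perfectly
concentrated") or 1 ("nothing to be uneven about") are both defensible and
offered as options. Writers serialize `NA` as an empty field, never 0 — the
distinction is semantic.

Species records *outside* the expected range are excluded from that species'
indices (the indices are defined relative to a static range expectation) and
reported in a diagnostics table, so range-map errors are auditable rather
than silently credited or lost.

Zero-record species stay in national means with coverage 0. Without this the
National SSII could not decline when sampling stops, and the index would be
a ratchet rather than a status indicator.

## Trends and typology

Annual national series are summarized over a decadal window by an OLS
regression of the index on year. The slope's two-sided *t*-test at
$\alpha = 0.01$ yields three classes: increasing, decreasing, none; fewer
than three annual values flags the series insufficient instead. A constant
series is reported as slope 0, class none, without relying on the degenerate
OLS fit. The test choice is deliberately ordinary: annual index series over
ten points carry little information, and OLS with a *t*-test is transparent
and has exact nominal error under Gaussian noise (verified by Monte-Carlo in
the test suite); Mann–Kendall is provided for monotone-but-nonlinear
trajectories.

Nations are then placed in four types by crossing decadal-mean Steward's
SSII against the global mean (the unweighted mean of national decadal
means) with the trend class: (1) below the mean, not increasing; (2) below,
increasing; (3) above, not increasing; (4) above, increasing. "Not
increasing" pools none and decreasing; "above" is a strict inequality, so a
nation exactly at the global mean falls on the "below" side. These
boundary rules are conventions — the data almost never sit exactly on a
boundary, but determinism requires picking a side.

The stewardship-preference diagnostic is the percent difference
$100(\mathrm{Steward's} - \mathrm{National})/\mathrm{National}$: positive
when a nation preferentially covers the species for which it holds a large
share of the global range. National SSII in the denominator makes the
number read as "percent better (or worse) than the unweighted baseline";
it is undefined when National SSII is 0.

## The synthetic-world generator

Real corpora of hundreds of millions of records cannot back a test suite, so
the package generates worlds whose structure mirrors the real layers while
every parameter is known:

* **Countries** are contiguous axis-aligned column bands tiling the grid —
  geographic realism is irrelevant to index arithmetic, exclusivity and
  full coverage are what matters.
* **Ranges** are connected cell blobs grown by random 4-neighbour accretion,
  with sizes drawn around a target mean.
* **Records** per species-year are Poisson with mean
  $\lambda (1+g)^t$ ($g$ = annual intensity trend), allocated over the
  range by a symmetric Dirichlet-multinomial with per-cell concentration
  $1/\theta$. One parameter thus spans the whole evenness axis:
  $\theta = 0$ is the uniform-multinomial limit (SSEI $\to$ 1 at high
  intensity), large $\theta$ piles records into one cell (SSII
  $\to 1/N$, SSEI $\to$ its floor). Mean SSEI is monotone non-increasing
  in $\theta$, which the suite checks by rank correlation across seeds.
* **Determinism.** All randomness flows from one seed through a separate
  derived stream per layer, so adding a layer does not shift existing draws
  and the same seed reproduces a world bit-identically.

Default test worlds are small (grids of order $10 \times 10$ cells, a
handful of countries, tens of species, $\lambda$ of order 10–500) — chosen
so properties are exercised across many seeds while the whole suite stays
quick on a laptop. What the synthetic worlds deliberately do *not* emulate:
detection processes, coordinate uncertainty, taxonomic error, range shifts,
or environmental covariates. Passing tests therefore demonstrate that the
indices compute what their definitions say on layers of the right shape —
not that the indices are robust to the quality problems of real occurrence
corpora, which the framework (by design) delegates to upstream cleaning.

The exact worked example (`fig1_fixture()`) is a fixed two-country,
two-species world — one endemic with 5 of 6 cells sampled, one wide-ranging
species with stewardship 0.3 and 2 of 3 national cells sampled — whose
computed indices are the canonical spot checks (0.83, 0.67, 0.2, 0.75,
0.8 after rounding; rounding is presentation only, all computation is at
full precision).

## Numerical notes and limitations

* Entropy uses natural logarithms throughout; normalization cancels the
  base, but fixing it keeps intermediate $H$ values reproducible.
* The stewardship sum identity holds to machine precision (asserted at
  1e-12), not approximately: it is set arithmetic, not estimation.
* Polygon-cell intersection areas are exact for simple rings under the
  chosen projection (Sutherland–Hodgman clipping against axis-aligned
  rectangles); near-ties in country assignment are rounded at 1e-9 of the
  cell fraction before the lexicographic tie-break so floating-point noise
  cannot decide them.
* One known evenness subtlety: with heavy redundancy (say 1000 records per
  redundant cell) the mixture curve of SSEI against the proportion of
  single-record cells is *not* monotone toward 1 — a small minority of
  heavily sampled cells dominates the record mass and keeps SSEI low right
  up to the uniform endpoint. The near-maximum behaviour at high
  single-record proportions holds only for light redundancy (2–10 records).
  The test suite asserts the curves' true ordering (heavier redundancy lies
  below lighter everywhere in the open interval).
* The indices inherit the limitations of their inputs: static range maps
  (no range dynamics), annual time slices (no seasonality or repeat-visit
  structure), geographic space only (no environmental-space coverage), and
  no detection-probability correction. These are properties of the
  indicator design, not implementation gaps.
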