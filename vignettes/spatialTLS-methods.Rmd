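---
title: "Detecting and classifying tertiary lymphoid structures from single-cell coordinates: methods and design notes"
author: "spatialTLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialTLS methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTLS)
```

## What the package computes

Multiplexed immunofluorescence of tumor sections yields, after
segmentation and positivity calling, a table of cells with 2-D
coordinates (microns) and binary marker flags. `spatialTLS` turns such
tables into the spatial immune-contexture readouts used in
high-grade serous ovarian cancer studies of chemotherapy-induced
immune remodeling:

* rule-based detection of **tertiary lymphoid structures (TLS)** —
  ectopic lymphoid aggregates — and their maturity classification
  (early vs mature, primary vs secondary follicle);
* per-phenotype **cell densities** (cells/mm²) by tumor-core /
  stroma compartment;
* **contact profiles** between tumor cells and T-cell subsets in
  concentric distance bins;
* **metagene signature scores** on log-scale expression matrices;
* **median-stratified survival analysis** (Kaplan–Meier, log-rank,
  univariate Cox).

A synthetic tissue and cohort generator with planted ground truth
drives all of it, so the full pipeline is testable end to end without
patient data.

## The TLS detection model

Cells are nodes of a *contact graph*: an undirected edge joins two
cells whose center distance is at most `contactDistanceUm`. Candidate
aggregates are the connected components of this graph. A component is
an accepted TLS when, in fixed filter order,

1. it has at least `minCells` cells (default 51, i.e. strictly more
   than 50),
2. its Feret diameter (maximum pairwise center distance) is at least
   `minExtentUm` (default 250 µm, boundary inclusive),
3. its CD20⁺ B-cell fraction strictly exceeds `bMajorityFraction`
   (default 0.5),
4. it contains at least one CD4⁺ and
5. at least one CD8⁺ cell.

The first failed filter is recorded as the rejection reason, and
rejected components are retained in the output, so every call is
auditable. Accepted TLS are classified by follicular dendritic cell
(FDC) content. Under the default `maturityRule = "follicle"`, any
CD21⁺CD23⁺ cell makes the aggregate a secondary-follicle mature TLS
(`mTLS_secondary`); otherwise any CD21⁺ cell makes it a
primary-follicle mature TLS (`mTLS_primary`); otherwise it is an early
TLS (`eTLS`). A stricter reading — maturity requires a CD21⁺CD23⁺
double-positive cell, CD21⁺-only aggregates staying early — is
available as `maturityRule = "strict_double_positive"`. Published
definitions state the two readings inconsistently; the package
implements both and defaults to the follicle reading, which treats the
primary follicle (CD21⁺ FDCs without CD23) as already mature.

### Why a 13 µm contact distance

The published aggregation criterion is phrased as close-proximity
contacts with a minimum gap of 3 µm. Three microns cannot be a
center-to-center distance for ~10 µm lymphocytes, so the package reads
it as a maximum membrane-to-membrane gap: with a nominal cell radius
of 5 µm the default center-to-center contact distance is
2·5 + 3 = 13 µm. The interpretation is explicit and the value is a
single tunable parameter of `detectorParams()`.

### Why the Feret diameter for "size"

The 250 µm minimum size is implemented as the maximum pairwise center
distance (Feret/caliper diameter) of the component. It is
rotation-invariant, scale-like, and cheap via the convex hull.
Bounding-box width and equivalent-circle diameter were considered and
rejected: the former is axis-dependent, the latter conflates size with
density.

## Phenotype gating

Phenotypes are **multilabel**: every rule (e.g. `CD8T` = CD8⁺,
`TCF1_PD1_CD8T` = TCF1⁺PD1⁺CD8⁺) gets its own boolean column, because
the populations of interest nest — every progenitor-exhausted
TCF1⁺PD1⁺CD8⁺ cell is also a PD1⁺CD8⁺ and a CD8⁺ cell, and densities
must count each population independently. A separate `primary_label`
(lowest priority number wins) exists only for reporting. Cells
positive for both TCF1 and TIM-3 stay in both exhaustion subsets:
the two states are defined independently and a tie-break would be
invented biology. The CD8⁺ gate does not exclude CD4⁺CD8⁺ double
positives. Intensity gating is inclusive (value ≥ cutoff ⇒ positive)
for deterministic boundary behavior.

## Spatial statistics

Densities are raw counts divided by region-polygon areas (µm² → mm²
by 10⁻⁶). When no region geometry is supplied, the whole-section area
falls back to the convex hull of all cells; the output flags this,
because hulls overestimate the area of sparse sections. No edge
correction is applied near section borders — the readouts mirror raw
published densities, and this is a documented limitation.

Contact profiles count (target, query) cell pairs per half-open
distance bin `[lo, hi)` (final bin closed), so no pair is ever
double-counted across bins; the default bins are 0–10–20–30 µm.
The "close proximity" estimator is the fraction of query cells with at
least one target strictly closer than 10 µm — strict `<`, matching the
printed inequality, and configurable. Whether published contact counts
are pair counts or query-cell counts is not stated; the package emits
both (per-bin pair counts and the close fraction) and asserts neither
as the canonical estimator.

Group comparisons use the two-sided Mann–Whitney test: full
enumeration of group assignments (ties included, via midrank U) when
both groups have fewer than 8 observations, otherwise the
tie-corrected normal approximation without continuity correction. The
Fisher test returns the conditional hypergeometric two-sided p (sum of
tables no more probable than the observed one) with the sample odds
ratio ad/bc.

## Survival analysis

Continuous scores are split at the sample median (midpoint convention
for even n); ties at the median go to the `Hi` group — a declared
convention, the source studies being silent. Kaplan–Meier curves use
the product-limit estimator with events preceding censorings at tied
times; the log-rank statistic is the standard hypergeometric
observed-vs-expected sum; Cox fits use Efron tie handling, Wald
p-values and normal-approximation 95% CIs `exp(β ± 1.96·se)`,
matching the "HR (95% CI)" presentation convention. The Kaplan–Meier,
log-rank and Cox machinery is delegated to the `survival` package;
the test suite pins each against hand-tabulated oracles.

## Signature scoring

The score of a gene set on a log-scale genes × samples matrix is the
mean of per-gene z-scores (each present gene row centered and scaled
across samples; constant rows dropped with a warning; absent genes
dropped, with coverage reported). A one-gene signature score is
exactly that gene's z-score. The aggregation rule behind published
signature levels is unstated; the z-mean is a declared, scale-free
choice common in metagene practice, not a claim of equivalence.
Built-ins: the 3-gene ER-stress module (DDIT3, HSPA5, HSP90B1) and the
12-chemokine TLS module (CCL2, CCL3, CCL4, CCL5, CCL8, CCL18, CCL19,
CCL21, CXCL9, CXCL10, CXCL11, CXCL13); user lists load from YAML.

## The synthetic-tissue generator

`simulateSlide()` composes three point processes on a rectangular
field (Cartesian microns, origin bottom-left, y up — a fixed
convention that removes image-axis ambiguity):

* homogeneous Poisson **background** per phenotype template
  (cells/mm²);
* **tumor nests**: PanCK⁺ cells uniform in discs;
* **planted TLS**: `nCells` cells inside a disc, placed by sequential
  random placement with a minimum-spacing rejection rule. A "skeleton"
  chain of cells along a randomly oriented diameter (spacing =
  `packingSpacingUm`, default 8 µm) pins the aggregate's extent at
  ~2·radius and guarantees connectivity; the remaining cells grow one
  at a time within packing spacing of an existing cell, never closer
  than half the spacing to any other. Pure hard-core rejection
  sampling would guarantee neither connectivity at the contact
  distance nor the 250 µm extent, which is why the skeleton variant is
  used.

Cell phenotypes inside a TLS follow the configured composition by
largest-remainder apportionment (deterministic), shuffled spatially;
the maturity class constrains FDC content (early: none;
mature-primary: ≥1 CD21⁺CD23⁻, no CD23⁺; mature-secondary: ≥1
CD21⁺CD23⁺). Marker noise is an independent symmetric flip per cell
per marker — the simplest model that exercises the robustness of the
majority/presence rules. Background and nest cells are cleared from a
guard ring (`guardMarginUm`, default 25 µm) around each TLS disc,
emulating the sharp demarcation of real aggregates and making planted
membership unambiguous; TLS discs may not overlap for the same reason.
Generation is a pure function of the config, including its seed.

Defaults are plausibility choices, the source material giving no
quantitative slide densities or TLS size distributions: background
infiltrate of tens of cells/mm² per population, TLS of 180–400 cells
with radius 130–150 µm, and B-cell fractions of 0.6–0.65 — TLS are
B-cell follicles and are strongly B-dominated — so that planted
aggregates pass the majority rule robustly at the simulated noise
levels.

**What the generator does not emulate:** continuous marker
intensities (beyond thresholdable values supplied by the user),
segmentation errors, irregular aggregate shapes, germinal-center
substructure, density gradients, spatially correlated noise, or 3-D
tissue. Passing recovery tests therefore demonstrates the correctness
of the rule implementations under the stated model, not detection
performance on real slides.

`simulateCohort()` draws exponential event times with hazard
`baselineHazard · exp(Σ β·x)` and independent exponential censoring —
exactly the model a univariate Cox fit assumes, which makes parameter
recovery a clean oracle. `simulateExpression()` plants a mean shift on
signature genes in one of two groups against standard-normal noise.

## Numerical conventions

* All boundary comparisons are documented above (inclusive gating,
  inclusive contact distance, inclusive minimum extent, strict B
  majority, strict close-proximity `<`, half-open bins, median ties to
  `Hi`).
* Points on a region-polygon boundary count as inside (closed
  polygons); tumor labels take precedence over stroma on overlap, so
  nests embedded in stroma resolve to tumor.
* Writers are deterministic: fixed column order, coordinates at fixed
  3-decimal (nm) precision, sorted JSON structure — reruns with the
  same config are byte-identical (manifest wall times aside).
* Components and calls are reported in a deterministic order (by
  smallest member cell id).

## Problem sizes in the test suite

The suite cross-checks the grid-indexed spatial code against
O(n²) brute-force oracles on slides of 200–2000 cells, recovers
planted TLS over 200 synthetic slides (plus 150 more across flip
rates 0/0.05/0.1), calibrates log-rank and Cox type-I error over 500
null cohorts of n = 60, recovers a planted hazard ratio of 2 over 100
cohorts of n = 4000, and measures signature power over 100 two-group
matrices of 50 + 50 samples. These sizes give standard errors well
inside the asserted tolerances while keeping the default test run
fast.

## Known limitations

* The contact-distance reading of the 3 µm criterion is an
  interpretation (membrane gap + nominal radius); centers, not
  membranes, are observed.
* No edge correction for densities and contacts near section borders.
* Aggregate detection is purely graph-based; density-based clustering
  (DBSCAN-style) and H&E-driven candidate proposal are out of scope.
* Region geometry is limited to simple (non-self-intersecting,
  hole-free) polygons.
* Published patient-level results (cohort hazard ratios, p-values)
  derive from biopsies that are not deposited and are not asserted as
  reproducible targets by this package.
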