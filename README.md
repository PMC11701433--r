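# spatialTLS

Rule-based detection of **tertiary lymphoid structures (TLS)** and the
surrounding spatial immune-contexture analysis for multiplexed
immunofluorescence of tumor sections — written for computational
pathology and tumor-immunology groups who have per-cell coordinate
tables (e.g. exported from HALO or QuPath after segmentation and
positivity calling) and want reproducible, auditable TLS calls,
densities, contact statistics and survival stratification in R.

## The model at the core

Cells are nodes of a contact graph with an edge wherever two cell
centers lie within a contact distance *d* (default 13 µm: a 3 µm
membrane gap plus two nominal 5 µm cell radii). Candidate aggregates
are the connected components. A component **A** is an accepted TLS iff

* |A| ≥ 51 (strictly more than 50 cells),
* Feret(A) ≥ 250 µm (maximum pairwise center distance),
* n(CD20⁺)/|A| > 0.5 (strict B-cell majority),
* n(CD4⁺) ≥ 1 and n(CD8⁺) ≥ 1,

with the first failed filter recorded as the rejection reason.
Accepted TLS are **mature** when they contain follicular dendritic
cells — `mTLS_secondary` if some cell is CD21⁺CD23⁺, else
`mTLS_primary` if some cell is CD21⁺, else **early** (`eTLS`). A
stricter maturity reading (a CD21⁺CD23⁺ cell required for any mature
call) is available as a parameter.

Around the detector: multilabel phenotype gating
(TCF1⁺PD1⁺CD8⁺ progenitor-exhausted vs TIM-3⁺PD1⁺CD8⁺ terminally
exhausted T cells, CXCR5⁺PD1⁺FoxP3⁻CD4⁺ T_FH, CD68⁺CD163⁺ M2-like
TAMs, ...), cells/mm² densities by tumor/stroma compartment, tumor
contact profiles in 0–10–20–30 µm bins, z-mean metagene scores
(built-in 3-gene ER-stress and 12-chemokine TLS signatures),
Mann–Whitney / Fisher exact tests, and median-cutoff Kaplan–Meier /
log-rank / Cox survival analysis. A synthetic slide-and-cohort
generator with planted ground truth exercises every stage. See the
methods vignette (`vignettes/spatialTLS-methods.Rmd`) for the design
rationale behind every threshold.

## Worked example

```r
library(spatialTLS)

## one synthetic 1.5 x 1.5 mm slide: immune background plus a planted
## mature TLS (320 cells, 140 um radius, 62% B cells, CD21+CD23+ FDCs)
comp <- c(Bcell = 0.62, CD4T = 0.15, CD8T = 0.12, TFH = 0.04,
          FDC21_23 = 0.02, other = 0.05)
cfg <- SlideConfig(
  fieldWidthUm = 1500, fieldHeightUm = 1500,
  backgroundRates = c(CD8T = 40, CD4T = 40, Bcell = 25, Tumor = 20),
  tlsSpecs = list(TLSSpec(center = c(500, 500), radiusUm = 140,
                          nCells = 320, composition = comp,
                          maturity = "mature_secondary")),
  seed = 11)
slide <- simulateSlide(cfg)
calls <- detectTLS(slide$table)
calls
#> TLSCallSet 'slide_seed11': 291 aggregate(s); eTLS=0, mTLS=1
subset(tlsCalls(calls), n_cells > 50)
#>   aggregate_id n_cells extent_um b_fraction n_cd4 n_cd8 n_cd21 n_cd23
#> 1      agg0001     320  280.0003   0.621875    61    38      6      6
#>   n_cd21_cd23 centroid_x centroid_y         status
#> 1           6   496.8529   499.3894 mTLS_secondary
```

The one multi-cell component (the 290 others are rejected background
singletons/pairs, kept for audit) spans 280 µm, is 62% CD20⁺ with CD4⁺
and CD8⁺ cells present, and carries six CD21⁺CD23⁺ follicular
dendritic cells — a secondary-follicle mature TLS, exactly as planted.

```r
## density comparison between two small groups (cells/mm^2)
compareGroups(c(210, 340, 520, 640), c(1150, 1340, 1480, 2100))
#> $U        [1] 0
#> $p        [1] 0.02857143      # exact enumeration, n < 8 per group
#> $method   [1] "exact"

## survival: planted protective effect of high mature-TLS burden
cohort <- simulateCohort(CohortConfig(
  nPatients = 300, baselineHazard = 0.06, logHr = c(mTLS_hi = log(0.5)),
  censorRate = 0.01,
  covariates = list(mTLS_hi = list(dist = "binary", p = 0.5)), seed = 5))
coxUnivariate(cohort, "mTLS_hi")
#> Cox fit [mTLS_hi]: HR 0.511 (95% CI 0.393-0.665), p = 5.739e-07
logrankTest(cohort, "mTLS_hi")$p
#> [1] 3.735284e-07
```

The fitted hazard ratio 0.51 recovers the planted log-HR of ln 0.5;
patients in the high-mTLS stratum halve their event hazard, and the
log-rank test agrees.

For the full pipeline, `simulateDemo("demo", seed = 1)` writes a
six-sample synthetic cohort (cell tables, region polygons, clinical
and expression tables, config), and
`runPipeline("demo/config.yaml", "out")` runs gate → phenotype →
compartments → TLS → densities → contacts → signatures → survival,
leaving tidy CSVs and a run manifest in `out/`.

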