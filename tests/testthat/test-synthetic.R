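test_that("an all-zero config yields an empty slide and empty truth", {
  sl <- simulateSlide(SlideConfig(1000, 1000, seed = 1))
  expect_equal(nCells(sl$table), 0L)
  expect_length(sl$truth, 0L)
})

test_that("a planted mature-secondary aggregate is generated exactly as specified", {
  comp <- c(Bcell = 0.6, CD4T = 0.15, CD8T = 0.12, TFH = 0.05,
            FDC21_23 = 0.03, other = 0.05)
  cfg <- SlideConfig(1200, 1200, tlsSpecs = list(
    TLSSpec(c(600, 600), 150, 400, comp, "mature_secondary",
            packingSpacingUm = 8)), seed = 42)
  sl <- simulateSlide(cfg)
  expect_length(sl$truth, 1L)
  expect_equal(sl$truth[[1L]]$status, "mTLS_secondary")
  expect_equal(nCells(sl$table), 400L)
  df <- cellData(sl$table)
  expect_setequal(df$cell_id, sl$truth[[1L]]$member_ids)
  ## no marker noise: planted flags are exact
  expect_gte(sum(df$CD21 == 1 & df$CD23 == 1), 1L)
  expect_gt(mean(df$CD20), 0.5)
  expect_gte(sum(df$CD4), 1L)
  expect_gte(sum(df$CD8), 1L)
  ## all cells inside the disc
  expect_true(all((df$x_um - 600)^2 + (df$y_um - 600)^2 <= 150.001^2))
})

test_that("maturity constrains the generated FDC content", {
  comp <- c(Bcell = 0.7, CD4T = 0.15, CD8T = 0.15)
  early <- simulateSlide(SlideConfig(1000, 1000, tlsSpecs = list(
    TLSSpec(c(500, 500), 130, 150, comp, "early")), seed = 5))
  df <- cellData(early$table)
  expect_equal(sum(df$CD21), 0L)
  expect_equal(sum(df$CD23), 0L)
  prim <- simulateSlide(SlideConfig(1000, 1000, tlsSpecs = list(
    TLSSpec(c(500, 500), 130, 150,
            c(comp * 0.97 / sum(comp), FDC21 = 0.03),
            "mature_primary")), seed = 5))
  dfp <- cellData(prim$table)
  expect_gte(sum(dfp$CD21 == 1 & dfp$CD23 == 0), 1L)
  expect_equal(sum(dfp$CD23), 0L)
})

test_that("background Poisson counts match the closed-form mean and dispersion", {
  ## 100 CD8 cells/mm^2 on a 2 x 2 mm field: Poisson mean 400
  counts <- vapply(1:200, function(s) {
    sl <- simulateSlide(SlideConfig(2000, 2000,
                                    backgroundRates = c(CD8T = 100),
                                    seed = s))
    sum(cellData(sl$table)$CD8 == 1)
  }, numeric(1L))
  se <- sqrt(400 / 200)
  expect_lt(abs(mean(counts) - 400), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("slide generation is a pure function of its config", {
  cfg <- plantedSlideConfig(7, 2L)
  a <- simulateSlide(cfg)
  b <- simulateSlide(cfg)
  expect_identical(cellData(a$table), cellData(b$table))
  expect_identical(a$truth, b$truth)
})

test_that("invalid slide geometry is rejected with the offending element named", {
  comp <- c(Bcell = 0.7, CD4T = 0.15, CD8T = 0.15)
  expect_error(SlideConfig(1000, 1000, tlsSpecs = list(
    TLSSpec(c(400, 500), 150, 60, comp, "early"),
    TLSSpec(c(600, 500), 150, 60, comp, "early"))), "1 and 2 overlap")
  expect_error(SlideConfig(1000, 1000, tlsSpecs = list(
    TLSSpec(c(50, 500), 150, 60, comp, "early"))), "outside the field")
  expect_error(SlideConfig(1000, 1000, markerFlipRate = 1.5), "\\[0, 1\\]")
  expect_error(TLSSpec(c(0, 0), 100, 50, c(Bcell = 0.5, CD4T = 0.4),
                       "early"), "sum to 1")
  expect_error(TLSSpec(c(0, 0), 100, 50, comp, "mature_secondary"),
               "FDC21_23")
})

test_that("simulated cohorts match the exponential model", {
  ## no censoring: every record is an event; mean time ~ 1/hazard
  ch <- simulateCohort(CohortConfig(5000, baselineHazard = 0.05,
                                    censorRate = 0, seed = 3))
  expect_true(all(ch$event == 1))
  se <- (1 / 0.05) / sqrt(5000)
  expect_lt(abs(mean(ch$time_months) - 20), 3 * se)
  ## censoring flags are consistent
  ch2 <- simulateCohort(CohortConfig(2000, baselineHazard = 0.05,
                                     censorRate = 0.05, seed = 4))
  expect_true(all(ch2$event %in% c(0, 1)))
  expect_gt(mean(ch2$event), 0.3)
  expect_lt(mean(ch2$event), 0.7)
  expect_identical(ch, simulateCohort(CohortConfig(5000,
                                                   baselineHazard = 0.05,
                                                   censorRate = 0,
                                                   seed = 3)))
})

test_that("expression simulation plants the group shift and validates input", {
  se <- simulateExpression(5L, "GENE1", shift = 0, nNoiseGenes = 0L,
                           seed = 1)
  expect_equal(nrow(se), 1L)
  expect_equal(ncol(se), 10L)
  expect_error(simulateExpression(5L, c("A", "A"), 1), "duplicate")
  expect_error(simulateExpression(1L, "A", 1), ">= 2")
  se2 <- simulateExpression(200L, "G", shift = 2, nNoiseGenes = 0L,
                            seed = 2)
  m <- SummarizedExperiment::assay(se2)
  grp <- SummarizedExperiment::colData(se2)$group
  expect_lt(abs(mean(m[, grp == "B"]) - mean(m[, grp == "A"]) - 2),
            3 * sqrt(2 / 200))
})
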