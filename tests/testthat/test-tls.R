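twoCells <- function(d) {
  CellTable(data.frame(cell_id = c("a", "b"), x_um = c(0, d), y_um = 0,
                       CD20 = 0L, CD4 = 0L, CD8 = 0L, CD21 = 0L,
                       CD23 = 0L), "s")
}

test_that("contact edges are inclusive at the distance threshold", {
  expect_equal(nrow(buildContactGraph(twoCells(13.0), 13.0)), 1L)
  expect_equal(nrow(buildContactGraph(twoCells(13.1), 13.0)), 0L)
  expect_error(buildContactGraph(twoCells(5), -1), "positive")
})

test_that("grid-indexed edges equal the all-pairs oracle on random slides", {
  for (seed in c(1, 2, 3)) {
    ct <- randomCellTable(500, seed = seed, width = 600, height = 600)
    df <- cellData(ct)
    got <- buildContactGraph(ct, 13)
    want <- bruteEdgeIndices(df$x_um, df$y_um, 13)
    gotIdx <- cbind(match(got$i, df$cell_id), match(got$j, df$cell_id))
    gotIdx <- gotIdx[order(gotIdx[, 1L], gotIdx[, 2L]), , drop = FALSE]
    expect_equal(unname(gotIdx), unname(cbind(want[, 1L], want[, 2L])))
    expect_equal(got$dist_um,
                 sqrt((df$x_um[gotIdx[, 1]] - df$x_um[gotIdx[, 2]])^2 +
                      (df$y_um[gotIdx[, 1]] - df$y_um[gotIdx[, 2]])^2))
  }
})

test_that("aggregates are the connected components, matching a union-find oracle", {
  ct <- randomCellTable(400, seed = 4, width = 800, height = 800)
  df <- cellData(ct)
  edges <- buildContactGraph(ct, 15)
  comps <- findAggregates(edges, ct)
  ## every cell in exactly one component
  expect_setequal(unlist(comps), df$cell_id)
  expect_equal(sum(lengths(comps)), nrow(df))
  want <- ufComponents(nrow(df),
                       cbind(match(edges$i, df$cell_id),
                             match(edges$j, df$cell_id)))
  wantIds <- lapply(want, function(ii) sort(df$cell_id[ii]))
  expect_setequal(lapply(comps, paste, collapse = "|"),
                  lapply(wantIds, paste, collapse = "|"))
  ## no edges: all singletons
  expect_length(findAggregates(buildContactGraph(ct, 0.001), ct), nrow(df))
})

test_that("classification applies the inclusion filters in fixed order with strict boundaries", {
  p <- detectorParams()
  classify <- function(ct) {
    classifyAggregate(cellData(ct)$cell_id, ct, p)$status
  }
  ## 50 cells is not 'more than 50'
  expect_equal(classify(lineAggregate(50, 260, nB = 30)),
               "rejected:min_cells")
  ## 51 cells passes size; all-else satisfied aggregate becomes eTLS
  expect_equal(classify(lineAggregate(51, 260, nB = 30)), "eTLS")
  ## extent boundary: 249.9 fails, 250.0 passes (inclusive)
  expect_equal(classify(lineAggregate(52, 249.9, nB = 30)),
               "rejected:min_extent")
  expect_equal(classify(lineAggregate(52, 250.0, nB = 30)), "eTLS")
  ## B-majority strict: 26/52 = 0.5 fails, 27/52 passes
  expect_equal(classify(lineAggregate(52, 260, nB = 26)),
               "rejected:b_majority")
  expect_equal(classify(lineAggregate(52, 260, nB = 27)), "eTLS")
  ## CD4 then CD8 presence
  expect_equal(classify(lineAggregate(52, 260, nB = 27, nCD4 = 0)),
               "rejected:no_cd4")
  expect_equal(classify(lineAggregate(52, 260, nB = 27, nCD8 = 0)),
               "rejected:no_cd8")
  ## first-failure reporting: too small AND too short reports min_cells
  expect_equal(classify(lineAggregate(40, 100, nB = 25)),
               "rejected:min_cells")
})

test_that("maturity transitions follow the follicle and strict double-positive readings", {
  p <- detectorParams()
  strict <- detectorParams(maturityRule = "strict_double_positive")
  st <- function(ct, pp) classifyAggregate(cellData(ct)$cell_id, ct, pp)$status
  none <- lineAggregate(60, 260, nB = 35)
  cd21 <- lineAggregate(60, 260, nB = 35, nCD21 = 1)
  dp <- lineAggregate(60, 260, nB = 35, nCD23dp = 1)
  expect_equal(st(none, p), "eTLS")
  expect_equal(st(cd21, p), "mTLS_primary")
  expect_equal(st(dp, p), "mTLS_secondary")
  ## stricter reading: maturity needs a CD21+CD23+ cell
  expect_equal(st(none, strict), "eTLS")
  expect_equal(st(cd21, strict), "eTLS")
  expect_equal(st(dp, strict), "mTLS_secondary")
})

test_that("detectTLS recovers a planted mixed slide and its fast path matches classifyAggregate", {
  sl <- simulateSlide(SlideConfig(2000, 2000,
    backgroundRates = c(CD8T = 30, Bcell = 20),
    tlsSpecs = list(
      TLSSpec(c(350, 350), 130, 200,
              c(Bcell = 0.62, CD4T = 0.15, CD8T = 0.12, FDC21_23 = 0.02,
                other = 0.09), "mature_secondary"),
      TLSSpec(c(350, 1650), 130, 200,
              c(Bcell = 0.62, CD4T = 0.15, CD8T = 0.12, FDC21 = 0.02,
                other = 0.09), "mature_primary"),
      TLSSpec(c(1650, 350), 130, 200,
              c(Bcell = 0.65, CD4T = 0.15, CD8T = 0.12, other = 0.08),
              "early")),
    seed = 21))
  cs <- detectTLS(sl$table)
  expect_equal(tlsSummary(cs), list(n_eTLS = 1L, n_mTLS = 2L,
                                    n_total_TLS = 3L))
  st <- recoveryStats(sl, cs)
  expect_equal(unname(st["tp"]), 3)
  ## fast aggregated path == per-component classification
  edges <- buildContactGraph(sl$table, 13)
  comps <- findAggregates(edges, sl$table)
  slow <- do.call(rbind, lapply(comps, classifyAggregate,
                                table = sl$table))
  fast <- tlsCalls(cs)[, setdiff(colnames(tlsCalls(cs)), "aggregate_id")]
  rownames(slow) <- rownames(fast) <- NULL
  expect_equal(fast, slow, tolerance = 1e-12)
  ## summary identity
  s <- tlsSummary(cs)
  expect_equal(s$n_total_TLS, s$n_eTLS + s$n_mTLS)
  ## accepted calls never share a cell
  acc <- tlsCalls(cs)$aggregate_id[!startsWith(tlsCalls(cs)$status,
                                               "rejected")]
  expect_false(anyDuplicated(unlist(tlsMembers(cs)[acc])) > 0)
})

test_that("component count is monotone in the contact distance and calls are rigid-motion invariant", {
  ct <- randomCellTable(400, seed = 12, width = 900, height = 900)
  nComp <- vapply(c(5, 10, 15, 25), function(r)
    length(findAggregates(buildContactGraph(ct, r), ct)), numeric(1L))
  expect_true(all(diff(nComp) <= 0))

  sl <- simulateSlide(plantedSlideConfig(31, 2L))
  base <- tlsCalls(detectTLS(sl$table))
  th <- 0.7; dx <- 311.5; dy <- -120.25
  df <- cellData(sl$table)
  rx <- cos(th) * df$x_um - sin(th) * df$y_um + dx
  ry <- sin(th) * df$x_um + cos(th) * df$y_um + dy
  df2 <- df; df2$x_um <- rx; df2$y_um <- ry
  moved <- tlsCalls(detectTLS(CellTable(df2, "s",
                                        markerNames = markerNames(sl$table))))
  expect_equal(moved$status, base$status)
  expect_equal(moved$n_cells, base$n_cells)
  expect_equal(moved$extent_um, base$extent_um, tolerance = 1e-6)
})
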