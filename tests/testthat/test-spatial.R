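sq <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

test_that("densities are count/area with region-based compartments", {
  set.seed(31)
  n <- 100L
  df <- data.frame(cell_id = sprintf("c%d", 1:n),
                   x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
                   CD8 = 1L)
  ct <- CellTable(df, "s")
  rs <- RegionSet(list(list(label = "tumor", coords = sq(0, 0, 1000, 1000))),
                  "s")
  dens <- computeDensities(ct, rs, phenotypes = "CD8")
  tum <- dens[dens$compartment == "tumor", ]
  expect_equal(tum$count, 100)
  expect_equal(tum$area_mm2, 1)
  expect_equal(tum$density_cells_per_mm2, 100)
  expect_equal(unique(dens$area_source), "regions")
  ## whole-section count = tumor + stroma + unassigned
  whole <- dens[dens$compartment == "whole", ]
  expect_equal(whole$count, 100)
})

test_that("hull fallback flags itself and rejects degenerate geometry", {
  df <- data.frame(cell_id = c("a", "b", "c"), x_um = c(0, 1, 2),
                   y_um = c(0, 1, 2), CD8 = 1L)
  expect_error(computeDensities(CellTable(df, "s"), phenotypes = "CD8"),
               "degenerate")
  set.seed(5)
  n <- 200L
  ct <- CellTable(data.frame(cell_id = sprintf("c%d", 1:n),
                             x_um = runif(n, 0, 1000),
                             y_um = runif(n, 0, 1000), CD8 = 1L), "s")
  dens <- computeDensities(ct, phenotypes = "CD8")
  expect_equal(dens$area_source, "hull")
  expect_equal(dens$count, n)
  expect_lt(dens$area_mm2, 1)
})

test_that("per-compartment density counts equal a brute-force point-in-polygon tally", {
  ct <- assignPhenotypes(randomCellTable(500, seed = 41))
  poly <- cbind(c(100, 800, 850, 300), c(50, 150, 800, 900))
  rs <- RegionSet(list(list(label = "tumor", coords = poly),
                       list(label = "tissue",
                            coords = sq(0, 0, 1000, 1000))), "s")
  dens <- computeDensities(ct, rs, phenotypes = c("Bcell", "CD8T"))
  df <- cellData(ct)
  inT <- vapply(seq_len(nrow(df)), function(i)
    pipOracle(df$x_um[i], df$y_um[i], poly), logical(1L))
  for (ph in c("Bcell", "CD8T")) {
    want <- sum(df[[ph]][inT])
    expect_equal(dens$count[dens$compartment == "tumor" &
                              dens$phenotype == ph], want, info = ph)
  }
})

test_that("contact bins are half-open with a strict close-proximity cutoff", {
  mk <- function(xq) CellTable(data.frame(
    cell_id = c("t1", "q1"), x_um = c(0, xq), y_um = 0,
    Tumor = c(1L, 0L), Q = c(0L, 1L)), "s")
  pr <- contactProfile(mk(5), "Tumor", "Q")
  expect_equal(pr$bins$count, c(1, 0, 0))
  expect_equal(pr$close_fraction, 1.0)
  ## exactly 10.0: falls in [10, 20), not 'close'
  pr10 <- contactProfile(mk(10), "Tumor", "Q")
  expect_equal(pr10$bins$count, c(0, 1, 0))
  expect_equal(pr10$close_fraction, 0.0)
  ## final bin inclusive of its upper edge
  pr30 <- contactProfile(mk(30), "Tumor", "Q")
  expect_equal(pr30$bins$count, c(0, 0, 1))
  expect_error(contactProfile(mk(5), "Tumor", "Q", c(0, 20, 10)),
               "strictly increasing")
})

test_that("contact profiles equal the all-pairs oracle and sum over disjoint queries", {
  ct <- assignPhenotypes(randomCellTable(800, seed = 17, width = 500,
                                         height = 500))
  df <- cellData(ct)
  pr <- contactProfile(ct, "Tumor", "Bcell")
  ti <- which(df$Tumor == 1); qi <- which(df$Bcell == 1)
  d <- sqrt(outer(df$x_um[ti], df$x_um[qi], "-")^2 +
            outer(df$y_um[ti], df$y_um[qi], "-")^2)
  d[outer(ti, qi, "==")] <- Inf
  want <- c(sum(d >= 0 & d < 10), sum(d >= 10 & d < 20),
            sum(d >= 20 & d <= 30))
  expect_equal(pr$bins$count, want)
  expect_equal(pr$close_fraction, mean(apply(d < 10, 2L, any)))
  ## counts cumulative-consistent and monotone in the outer edge
  one <- contactProfile(ct, "Tumor", "Bcell", c(0, 30))
  expect_equal(one$bins$count, sum(pr$bins$count))
  ## disjoint queries: profile on the union = sum of profiles
  df$EITHER <- as.integer((df$TCF1_PD1_CD8T | df$TIM3_PD1_CD8T) &
                            !(df$TCF1_PD1_CD8T & df$TIM3_PD1_CD8T))
  df$ONLY_T <- as.integer(df$TCF1_PD1_CD8T & !df$TIM3_PD1_CD8T)
  df$ONLY_M <- as.integer(df$TIM3_PD1_CD8T & !df$TCF1_PD1_CD8T)
  ct2 <- CellTable(df, "s", markerNames = markerNames(ct))
  u <- contactProfile(ct2, "Tumor", "EITHER")
  a <- contactProfile(ct2, "Tumor", "ONLY_T")
  b <- contactProfile(ct2, "Tumor", "ONLY_M")
  expect_equal(u$bins$count, a$bins$count + b$bins$count)
})

test_that("Mann-Whitney p-values match enumeration and the reference implementation", {
  ## identical constant samples carry no evidence
  expect_equal(compareGroups(rep(2, 5), rep(2, 5))$p, 1.0)
  ## textbook fully separated case: U = 0, exact p = 2/20
  r <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  ## exact branch equals an independent pair-counting enumeration (with ties)
  set.seed(9)
  for (k in 1:10) {
    a <- sample(1:6, sample(3:6, 1L), replace = TRUE)
    b <- sample(1:6, sample(3:6, 1L), replace = TRUE)
    want <- mwEnumOracle(a, b)
    got <- compareGroups(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p)
  }
  ## large-sample branch matches wilcox.test's tie-corrected normal approx
  set.seed(10)
  for (k in 1:5) {
    a <- round(rnorm(30), 1)
    b <- round(rnorm(30, 0.4), 1)
    got <- compareGroups(a, b)
    want <- suppressWarnings(wilcox.test(a, b, correct = FALSE,
                                         exact = FALSE))
    expect_equal(got$p, unname(want$p.value), tolerance = 1e-8)
    expect_equal(got$U, unname(want$statistic))
  }
  expect_error(compareGroups(numeric(0), 1), "empty")
})

test_that("Fisher exact p equals the hypergeometric reference; OR is ad/bc", {
  r <- fisher2x2(5, 0, 0, 5)
  expect_equal(r$odds_ratio, Inf)
  expect_equal(r$p, 2 / 252)
  r2 <- fisher2x2(2, 2, 2, 2)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1.0)
  set.seed(11)
  for (k in 1:25) {
    tb <- rpois(4, 4)
    if (sum(tb) == 0) next
    got <- fisher2x2(tb[1], tb[2], tb[3], tb[4])
    want <- fisher.test(matrix(tb, 2L, byrow = TRUE))
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }
  expect_error(fisher2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher2x2(-1, 0, 0, 1), "non-negative")
})
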