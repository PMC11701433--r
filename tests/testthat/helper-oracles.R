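## Independent oracles used to cross-check the package's spatial code paths.

## all-pairs fixed-radius neighbor oracle built on stats::dist
bruteEdgeIndices <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  dm <- as.matrix(stats::dist(cbind(x, y)))
  hit <- which(upper.tri(dm) & dm <= r, arr.ind = TRUE)
  m <- cbind(i = pmin(hit[, 1L], hit[, 2L]), j = pmax(hit[, 1L], hit[, 2L]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

## union-find connected components (path halving), independent of igraph
ufComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  unname(split(seq_len(n), roots))
}

## scalar point-in-polygon oracle (crossing number + point-to-segment
## distance for the boundary), deliberately a different formulation from
## the package's vectorized ray casting
pipOracle <- function(px, py, poly) {
  n <- nrow(poly)
  cnt <- 0L
  on <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
    L2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (L2 == 0) 0 else
      max(0, min(1, ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / L2))
    dx <- px - (x1 + t * (x2 - x1)); dy <- py - (y1 + t * (y2 - y1))
    if (dx * dx + dy * dy < 1e-16) on <- TRUE
    if ((y1 <= py) != (y2 <= py)) {
      xin <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xin) cnt <- cnt + 1L
    }
  }
  on || (cnt %% 2L == 1L)
}

## pair-counting Mann-Whitney U with full-enumeration two-sided p,
## defined directly from the (a > b) + 0.5 (a == b) pair count
mwEnumOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  uOf <- function(idx) {
    av <- pooled[idx]; bv <- pooled[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  uObs <- uOf(seq_len(n1))
  mu <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2L, uOf)
  list(U = uObs, p = mean(abs(us - mu) >= abs(uObs - mu) - 1e-9))
}

## random gated cell table with independent marker flags
randomCellTable <- function(n, seed, width = 1000, height = 1000,
                            markerProbs = c(CD20 = 0.3, CD4 = 0.2,
                                            CD8 = 0.2, CD21 = 0.05,
                                            CD23 = 0.05, PD1 = 0.2,
                                            TCF1 = 0.1, `TIM-3` = 0.1,
                                            PanCK = 0.25)) {
  ## remaining panel markers at a low background positivity
  rest <- setdiff(markerUniverse(), names(markerProbs))
  markerProbs <- c(markerProbs, setNames(rep(0.05, length(rest)), rest))
  set.seed(seed)
  df <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                   x_um = round(runif(n, 0, width), 3L),
                   y_um = round(runif(n, 0, height), 3L),
                   check.names = FALSE)
  for (mk in names(markerProbs))
    df[[mk]] <- rbinom(n, 1L, markerProbs[[mk]])
  CellTable(df, sampleId = paste0("rand", seed))
}

## a straight-line aggregate with controlled size, extent and composition;
## cells spaced so the chain is connected at the default contact distance
lineAggregate <- function(n, extent, nB, nCD4 = 2L, nCD8 = 2L,
                          nCD21 = 0L, nCD23dp = 0L) {
  stopifnot(nB + nCD4 + nCD8 <= n, nCD21 + nCD23dp <= n)
  xs <- seq(0, extent, length.out = n)
  df <- data.frame(cell_id = sprintf("L%04d", seq_len(n)), x_um = xs,
                   y_um = 0, CD20 = 0L, CD4 = 0L, CD8 = 0L, CD21 = 0L,
                   CD23 = 0L)
  lab <- rep("other", n)
  lab[seq_len(nB)] <- "B"
  if (nCD4) lab[nB + seq_len(nCD4)] <- "CD4"
  if (nCD8) lab[nB + nCD4 + seq_len(nCD8)] <- "CD8"
  df$CD20[lab == "B"] <- 1L
  df$CD4[lab == "CD4"] <- 1L
  df$CD8[lab == "CD8"] <- 1L
  if (nCD21) df$CD21[n - seq_len(nCD21) + 1L] <- 1L
  if (nCD23dp) {
    ii <- n - nCD21 - seq_len(nCD23dp) + 1L
    df$CD21[ii] <- 1L
    df$CD23[ii] <- 1L
  }
  CellTable(df, sampleId = "line")
}

## planted-slide config used by recovery tests: up to 4 well-separated TLS
## on a 2 x 2 mm field, B-dominated composition, maturities cycling
plantedSlideConfig <- function(seed, nTls, flipRate = 0) {
  centers <- list(c(350, 350), c(350, 1650), c(1650, 350), c(1650, 1650))
  mats <- c("early", "mature_primary", "mature_secondary")
  comp <- function(m) {
    base <- c(Bcell = 0.65, CD4T = 0.12, CD8T = 0.10, TFH = 0.04,
              other = 0.09)
    extra <- switch(m, early = c(),
                    mature_primary = c(FDC21 = 0.03),
                    mature_secondary = c(FDC21 = 0.015, FDC21_23 = 0.015))
    out <- c(base, extra)
    out / sum(out)
  }
  specs <- lapply(seq_len(nTls), function(k) {
    m <- mats[((seed + k) %% 3L) + 1L]
    TLSSpec(centers[[k]], radiusUm = 130, nCells = 180L + 20L * k,
            composition = comp(m), maturity = m)
  })
  SlideConfig(2000, 2000,
              backgroundRates = c(CD8T = 30, CD4T = 30, Bcell = 20,
                                  Tumor = 15, other = 30),
              tlsSpecs = specs, markerFlipRate = flipRate, seed = seed)
}

## fraction of planted aggregates recovered as accepted TLS calls with
## exactly the planted membership, plus precision over accepted calls
recoveryStats <- function(slide, callset, requireStatus = TRUE) {
  calls <- tlsCalls(callset)
  acc <- calls[!startsWith(calls$status, "rejected"), , drop = FALSE]
  mem <- tlsMembers(callset)
  tp <- 0L
  for (tr in slide$truth) {
    hit <- FALSE
    for (k in seq_len(nrow(acc))) {
      if (setequal(mem[[acc$aggregate_id[k]]], tr$member_ids) &&
          (!requireStatus || acc$status[k] == tr$status)) {
        hit <- TRUE
        break
      }
    }
    tp <- tp + hit
  }
  c(n_truth = length(slide$truth), n_accepted = nrow(acc), tp = tp)
}
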