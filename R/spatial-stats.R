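#' @include AllClasses.R
NULL

regionAreaMm2 <- function(regions, labels) {
  polys <- Filter(function(p) p$label %in% labels, regions@polygons)
  sum(vapply(polys, function(p) polygonArea(p$coords), numeric(1L))) * 1e-6
}

#' Per-phenotype cell densities (cells/mm^2) by compartment
#'
#' With regions, compartment areas come from the polygons (tumor area =
#' sum of tumor polygons; stroma area = sum of stroma and tissue polygons;
#' whole = their total) and cells are assigned to compartments by
#' point-in-polygon; without regions only the whole-section report is
#' produced, with the convex-hull area of all cells (flagged in the
#' output, since hulls overestimate sparse-section area). No edge
#' correction is applied near the section border.
#'
#' @param table phenotyped \linkS4class{CellTable}.
#' @param regions optional \linkS4class{RegionSet}.
#' @param phenotypes names of logical/binary phenotype columns to tally
#'   (default: the \code{\link{defaultRules}} names present in the table).
#' @return Tidy data.frame: \code{sample_id}, \code{compartment}
#'   (\code{tumor}/\code{stroma}/\code{whole}), \code{phenotype},
#'   \code{count}, \code{area_mm2}, \code{density_cells_per_mm2},
#'   \code{area_source} (\code{regions} or \code{hull}).
#' @export
computeDensities <- function(table, regions = NULL, phenotypes = NULL) {
  stopifnot(is(table, "CellTable"))
  df <- table@cells
  if (is.null(phenotypes)) {
    nm <- vapply(defaultRules(), `[[`, character(1L), "name")
    phenotypes <- intersect(nm, colnames(df))
  }
  miss <- setdiff(phenotypes, colnames(df))
  if (length(miss)) stopf("phenotype column '%s' missing", miss[1L])
  countIn <- function(rows) vapply(phenotypes, function(ph)
    sum(df[[ph]][rows] == 1), numeric(1L))
  out <- list()
  if (!is.null(regions) && length(regions@polygons)) {
    table <- assignCompartments(table, regions)
    df <- table@cells
    areas <- c(tumor = regionAreaMm2(regions, "tumor"),
               stroma = regionAreaMm2(regions, c("stroma", "tissue")))
    areas <- c(areas, whole = sum(areas))
    rowsets <- list(tumor = which(df$compartment == "tumor"),
                    stroma = which(df$compartment == "stroma"),
                    whole = seq_len(nrow(df)))
    for (comp in names(rowsets)) {
      a <- areas[[comp]]
      if (a <= 0) {
        if (comp == "whole") stopf("zero total region area")
        next
      }
      cnt <- countIn(rowsets[[comp]])
      out[[comp]] <- data.frame(sample_id = table@sampleId,
                                compartment = comp, phenotype = phenotypes,
                                count = cnt, area_mm2 = a,
                                density_cells_per_mm2 = cnt / a,
                                area_source = "regions",
                                stringsAsFactors = FALSE, row.names = NULL)
    }
  } else {
    if (nrow(df) < 3L) stopf("need >= 3 cells for a hull-based area")
    h <- grDevices::chull(df$x_um, df$y_um)
    a <- if (length(h) >= 3L)
      polygonArea(cbind(df$x_um[h], df$y_um[h])) * 1e-6 else 0
    if (a <= 0) stopf("degenerate convex hull (zero area)")
    cnt <- countIn(seq_len(nrow(df)))
    out$whole <- data.frame(sample_id = table@sampleId, compartment = "whole",
                            phenotype = phenotypes, count = cnt,
                            area_mm2 = a, density_cells_per_mm2 = cnt / a,
                            area_source = "hull", stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contact profile between a target and a query phenotype
#'
#' Counts (target, query) cell pairs with center distance in half-open
#' bins [lo, hi) (final bin inclusive of its upper edge); a cell that
#' carries both phenotypes is never paired with itself. Also reports the
#' fraction of query cells having at least one target strictly closer
#' than \code{closeDistUm} (the "close proximity" estimator; strict <,
#' so a pair at exactly the cutoff does not count).
#'
#' @param table phenotyped \linkS4class{CellTable}.
#' @param targetPhenotype,queryPhenotype binary/logical columns of the
#'   table (default target: \code{Tumor}).
#' @param binEdges strictly increasing distance-bin edges starting at 0
#'   (microns).
#' @param closeDistUm close-proximity cutoff (microns).
#' @return List of class \code{ContactProfile}: \code{sample_id},
#'   \code{bins} (data.frame lo/hi/count), \code{n_targets},
#'   \code{n_queries}, \code{close_fraction}.
#' @export
contactProfile <- function(table, targetPhenotype = "Tumor",
                           queryPhenotype, binEdges = c(0, 10, 20, 30),
                           closeDistUm = 10) {
  stopifnot(is(table, "CellTable"))
  df <- table@cells
  for (ph in c(targetPhenotype, queryPhenotype))
    if (!ph %in% colnames(df)) stopf("phenotype column '%s' missing", ph)
  if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
    stopf("bin edges must be strictly increasing")
  if (binEdges[1L] != 0) stopf("bin edges must start at 0")
  ti <- which(df[[targetPhenotype]] == 1)
  qi <- which(df[[queryPhenotype]] == 1)
  nb <- length(binEdges) - 1L
  counts <- rep(0, nb)
  closeHit <- logical(length(qi))
  if (length(ti) && length(qi)) {
    rmax <- max(binEdges[length(binEdges)], closeDistUm)
    ## chunk the query side to bound the distance-matrix size
    chunk <- max(1L, floor(5e6 / length(ti)))
    for (s in seq(1L, length(qi), by = chunk)) {
      idx <- qi[s:min(s + chunk - 1L, length(qi))]
      dx <- outer(df$x_um[ti], df$x_um[idx], "-")
      dy <- outer(df$y_um[ti], df$y_um[idx], "-")
      d <- sqrt(dx * dx + dy * dy)
      self <- outer(ti, idx, "==")
      d[self] <- Inf
      for (b in seq_len(nb)) {
        inBin <- d >= binEdges[b] &
          (if (b == nb) d <= binEdges[b + 1L] else d < binEdges[b + 1L])
        counts[b] <- counts[b] + sum(inBin)
      }
      closeHit[s:(s + length(idx) - 1L)] <-
        apply(d < closeDistUm, 2L, any)
    }
  }
  structure(list(sample_id = table@sampleId,
                 target = targetPhenotype, query = queryPhenotype,
                 bins = data.frame(lo_um = binEdges[-length(binEdges)],
                                   hi_um = binEdges[-1L], count = counts),
                 n_targets = length(ti), n_queries = length(qi),
                 close_dist_um = closeDistUm,
                 close_fraction = if (length(qi)) mean(closeHit) else NA_real_),
            class = "ContactProfile")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by full enumeration of group assignments when both groups have
#' fewer than 8 observations (ties handled through midrank U), otherwise
#' the tie-corrected normal approximation (no continuity correction).
#' The two-sided exact p sums the probability of assignments whose U is
#' at least as far from the null mean as the observed U.
#'
#' @param valuesA,valuesB numeric samples (each nonempty).
#' @return list with \code{U} (U statistic of group A), \code{p} and
#'   \code{method} (\code{exact} or \code{normal}).
#' @export
compareGroups <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB)) stopf("empty group")
  n1 <- length(valuesA); n2 <- length(valuesB)
  pooled <- c(valuesA, valuesB)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 < 8L && n2 < 8L) {
    combs <- combn(n1 + n2, n1)
    uAll <- apply(combs, 2L, function(idx)
      sum(rk[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(uAll - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact")
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu) / sqrt(sig2)
    list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional hypergeometric test: the p-value sums the probabilities of
#' all tables (with the observed margins) whose probability does not
#' exceed the observed table's. The odds ratio is the sample ad/bc (with
#' 0 and Inf handled at zero cells), not the conditional MLE.
#'
#' @param a,b,c,d non-negative integer cell counts (rows = group,
#'   columns = outcome).
#' @return list with \code{odds_ratio} and \code{p}.
#' @export
fisher2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be non-negative integers")
  if (sum(cells) == 0) stopf("all-zero table")
  orv <- if (b * c == 0 && a * d == 0) NaN
         else if (b * c == 0) Inf
         else (a * d) / (b * c)
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  pObs <- stats::dhyper(a, m1, m2, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  list(odds_ratio = orv, p = min(1, p))
}

#' @export
print.ContactProfile <- function(x, ...) {
  cat("ContactProfile '", x$sample_id, "': ", x$target, " -> ", x$query,
      " (", x$n_targets, " targets, ", x$n_queries, " queries)\n", sep = "")
  print(x$bins)
  cat("close_fraction (<", x$close_dist_um, " um): ", x$close_fraction,
      "\n", sep = "")
  invisible(x)
}
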