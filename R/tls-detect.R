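#' @include AllClasses.R
NULL

#' Detector parameters for TLS calling
#'
#' The detection rule set: cells whose centers lie within
#' \code{contactDistanceUm} of each other are "in contact"; connected
#' components of the contact graph are candidate aggregates; an aggregate
#' is an accepted TLS when it has at least \code{minCells} cells, a Feret
#' extent of at least \code{minExtentUm}, a CD20+ B-cell fraction strictly
#' above \code{bMajorityFraction}, and (by default) at least one CD4+ and
#' one CD8+ cell. Accepted TLS are mature when they contain follicular
#' dendritic cells: under the default \code{maturityRule = "follicle"},
#' any CD21+CD23+ cell makes the aggregate a secondary-follicle mTLS, else
#' any CD21+ cell a primary-follicle mTLS, else it is an early TLS. Under
#' \code{"strict_double_positive"} only a CD21+CD23+ cell confers
#' maturity (an aggregate with CD21+-only cells stays early).
#'
#' The published contact criterion is a maximum membrane-to-membrane gap
#' of 3 um; with a nominal cell radius of 5 um this gives the default
#' center-to-center contact distance of 13 um, exposed here as a single
#' tunable parameter.
#'
#' @param contactDistanceUm center-to-center contact distance, microns.
#' @param minCells minimum member count of an accepted TLS (default 51,
#'   i.e. strictly more than 50 cells).
#' @param minExtentUm minimum Feret diameter (max pairwise center
#'   distance), microns; boundary inclusive.
#' @param bMajorityFraction accepted TLS need B fraction strictly above
#'   this (default 0.5).
#' @param requireCd4,requireCd8 require at least one CD4+ / CD8+ member.
#' @param maturityRule \code{"follicle"} or \code{"strict_double_positive"}.
#' @return Classed list of validated parameters.
#' @export
detectorParams <- function(contactDistanceUm = 13.0, minCells = 51L,
                           minExtentUm = 250.0, bMajorityFraction = 0.5,
                           requireCd4 = TRUE, requireCd8 = TRUE,
                           maturityRule = c("follicle",
                                            "strict_double_positive")) {
  maturityRule <- match.arg(maturityRule)
  if (contactDistanceUm <= 0) stopf("contactDistanceUm must be positive")
  if (minCells < 1L) stopf("minCells must be >= 1")
  if (minExtentUm < 0) stopf("minExtentUm must be >= 0")
  if (bMajorityFraction <= 0 || bMajorityFraction >= 1)
    stopf("bMajorityFraction must be in (0, 1)")
  structure(list(contact_distance_um = as.numeric(contactDistanceUm),
                 min_cells = as.integer(minCells),
                 min_extent_um = as.numeric(minExtentUm),
                 b_majority_fraction = as.numeric(bMajorityFraction),
                 require_cd4 = isTRUE(requireCd4),
                 require_cd8 = isTRUE(requireCd8),
                 maturity_rule = maturityRule),
            class = "DetectorParams")
}

#' Build the cell-contact graph
#'
#' Undirected edge (i, j) iff the Euclidean center distance is at most
#' \code{contactDistanceUm} (boundary inclusive); no self-edges. Uses a
#' grid-bucket fixed-radius neighbor search.
#'
#' @param table a \linkS4class{CellTable}.
#' @param contactDistanceUm positive contact distance in microns.
#' @return data.frame with columns \code{i}, \code{j} (cell ids, i from an
#'   earlier row than j) and \code{dist_um}.
#' @export
buildContactGraph <- function(table, contactDistanceUm = 13.0) {
  stopifnot(is(table, "CellTable"))
  if (!is.finite(contactDistanceUm) || contactDistanceUm <= 0)
    stopf("contact distance must be positive")
  df <- table@cells
  prs <- neighborPairs(df$x_um, df$y_um, contactDistanceUm)
  d <- sqrt((df$x_um[prs[, 1L]] - df$x_um[prs[, 2L]])^2 +
            (df$y_um[prs[, 1L]] - df$y_um[prs[, 2L]])^2)
  data.frame(i = df$cell_id[prs[, 1L]], j = df$cell_id[prs[, 2L]],
             dist_um = d, stringsAsFactors = FALSE)
}

#' Partition cells into contact-graph components
#'
#' Connected components of the contact graph, singletons included,
#' reported in deterministic order (by smallest member cell id; members
#' sorted within each component).
#'
#' @param edges edge data.frame from \code{\link{buildContactGraph}}.
#' @param table the \linkS4class{CellTable} the edges were built from.
#' @return list of character vectors of member cell ids.
#' @export
findAggregates <- function(edges, table) {
  stopifnot(is(table, "CellTable"))
  ids <- table@cells$cell_id
  if (!length(ids)) return(list())
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership[ids])
  groups <- lapply(groups, function(v) sort(unname(v)))
  groups <- groups[order(vapply(groups, `[`, character(1L), 1L))]
  unname(groups)
}

rejectedStatus <- function(reason) paste0("rejected:", reason)

#' Classify one aggregate against the TLS rules
#'
#' Computes size, Feret extent, CD20+ B fraction, CD4/CD8 presence and
#' CD21/CD23 counts, then applies the acceptance filters in fixed order
#' (size, extent, B majority, CD4 presence, CD8 presence), recording the
#' first failed rule as \code{rejected:<reason>}. Survivors are classified
#' by the maturity rule of \code{params} (see \code{\link{detectorParams}}).
#'
#' @param memberIds cell ids of the aggregate (nonempty).
#' @param table gated \linkS4class{CellTable} carrying the CD20, CD4, CD8,
#'   CD21 and CD23 marker columns.
#' @param params a \code{\link{detectorParams}} list.
#' @return One-row data.frame of TLSCall fields.
#' @export
classifyAggregate <- function(memberIds, table, params = detectorParams()) {
  stopifnot(is(table, "CellTable"), length(memberIds) >= 1L)
  df <- table@cells
  need <- c("CD20", "CD4", "CD8", "CD21", "CD23")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("marker column '%s' missing", miss[1L])
  sub <- df[match(memberIds, df$cell_id), , drop = FALSE]
  if (anyNA(sub$cell_id)) stopf("unknown member cell id")
  n <- nrow(sub)
  extent <- feretDiameter(sub$x_um, sub$y_um)
  bFrac <- sum(sub$CD20 == 1) / n
  nCd4 <- sum(sub$CD4 == 1)
  nCd8 <- sum(sub$CD8 == 1)
  nCd21 <- sum(sub$CD21 == 1)
  nCd23 <- sum(sub$CD23 == 1)
  nCd2123 <- sum(sub$CD21 == 1 & sub$CD23 == 1)
  status <- if (n < params$min_cells) rejectedStatus("min_cells")
    else if (extent < params$min_extent_um) rejectedStatus("min_extent")
    else if (bFrac <= params$b_majority_fraction) rejectedStatus("b_majority")
    else if (params$require_cd4 && nCd4 < 1L) rejectedStatus("no_cd4")
    else if (params$require_cd8 && nCd8 < 1L) rejectedStatus("no_cd8")
    else if (nCd2123 >= 1L) "mTLS_secondary"
    else if (params$maturity_rule == "follicle" && nCd21 >= 1L) "mTLS_primary"
    else "eTLS"
  data.frame(n_cells = n, extent_um = extent, b_fraction = bFrac,
             n_cd4 = nCd4, n_cd8 = nCd8, n_cd21 = nCd21, n_cd23 = nCd23,
             n_cd21_cd23 = nCd2123, centroid_x = mean(sub$x_um),
             centroid_y = mean(sub$y_um), status = status,
             stringsAsFactors = FALSE)
}

#' Detect and classify TLS on a slide
#'
#' Full pipeline: contact graph, connected components, per-aggregate
#' classification. All components (including rejected ones, with their
#' rejection reason) are retained for auditability.
#'
#' @param table gated \linkS4class{CellTable}.
#' @param params a \code{\link{detectorParams}} list.
#' @return A \linkS4class{TLSCallSet}; \code{\link{tlsSummary}} gives
#'   \code{n_eTLS}, \code{n_mTLS} and \code{n_total_TLS}.
#' @export
detectTLS <- function(table, params = detectorParams()) {
  stopifnot(is(table, "CellTable"))
  edges <- buildContactGraph(table, params$contact_distance_um)
  comps <- findAggregates(edges, table)
  if (length(comps)) {
    df <- table@cells
    need <- c("CD20", "CD4", "CD8", "CD21", "CD23")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stopf("marker column '%s' missing", miss[1L])
    ## vectorized per-component tallies (equivalent to classifyAggregate
    ## on each component; the equivalence is pinned in the test suite)
    lens <- lengths(comps)
    allIdx <- match(unlist(comps), df$cell_id)
    if (anyNA(allIdx)) stopf("unknown member cell id")
    grp <- rep(seq_along(comps), lens)
    tally <- function(v) rowsum(as.numeric(v), grp)[, 1L]
    n <- as.integer(lens)
    nCd20 <- tally(df$CD20[allIdx] == 1)
    nCd4 <- tally(df$CD4[allIdx] == 1)
    nCd8 <- tally(df$CD8[allIdx] == 1)
    nCd21 <- tally(df$CD21[allIdx] == 1)
    nCd23 <- tally(df$CD23[allIdx] == 1)
    nCd2123 <- tally(df$CD21[allIdx] == 1 & df$CD23[allIdx] == 1)
    cx <- tally(df$x_um[allIdx]) / n
    cy <- tally(df$y_um[allIdx]) / n
    idxSplit <- split(allIdx, grp)
    extent <- vapply(idxSplit, function(ii)
      feretDiameter(df$x_um[ii], df$y_um[ii]), numeric(1L))
    bFrac <- nCd20 / n
    status <- ifelse(n < params$min_cells, rejectedStatus("min_cells"),
      ifelse(extent < params$min_extent_um, rejectedStatus("min_extent"),
      ifelse(bFrac <= params$b_majority_fraction,
             rejectedStatus("b_majority"),
      ifelse(params$require_cd4 & nCd4 < 1L, rejectedStatus("no_cd4"),
      ifelse(params$require_cd8 & nCd8 < 1L, rejectedStatus("no_cd8"),
      ifelse(nCd2123 >= 1L, "mTLS_secondary",
      ifelse(params$maturity_rule == "follicle" & nCd21 >= 1L,
             "mTLS_primary", "eTLS")))))))
    calls <- data.frame(aggregate_id = sprintf("agg%04d", seq_along(comps)),
                        n_cells = n, extent_um = unname(extent),
                        b_fraction = bFrac, n_cd4 = as.integer(nCd4),
                        n_cd8 = as.integer(nCd8),
                        n_cd21 = as.integer(nCd21),
                        n_cd23 = as.integer(nCd23),
                        n_cd21_cd23 = as.integer(nCd2123),
                        centroid_x = cx, centroid_y = cy, status = status,
                        stringsAsFactors = FALSE, row.names = NULL)
    members <- comps
    names(members) <- calls$aggregate_id
  } else {
    calls <- data.frame(aggregate_id = character(0), n_cells = integer(0),
                        extent_um = numeric(0), b_fraction = numeric(0),
                        n_cd4 = integer(0), n_cd8 = integer(0),
                        n_cd21 = integer(0), n_cd23 = integer(0),
                        n_cd21_cd23 = integer(0), centroid_x = numeric(0),
                        centroid_y = numeric(0), status = character(0),
                        stringsAsFactors = FALSE)
    members <- list()
  }
  new("TLSCallSet", sampleId = table@sampleId, calls = calls,
      members = members, params = unclass(params))
}

#' Write TLS calls to CSV plus a member-id sidecar JSON
#'
#' @param callset a \linkS4class{TLSCallSet}.
#' @param csvPath per-call CSV output path.
#' @param membersPath sidecar JSON path mapping aggregate_id to member ids;
#'   defaults to \code{csvPath} with a \code{_members.json} suffix.
#' @return \code{csvPath}, invisibly.
#' @export
writeTLSCalls <- function(callset, csvPath,
                          membersPath = sub("\\.csv$", "_members.json",
                                            csvPath)) {
  stopifnot(is(callset, "TLSCallSet"))
  calls <- callset@calls
  for (cc in c("extent_um", "b_fraction", "centroid_x", "centroid_y"))
    calls[[cc]] <- sprintf("%.6f", calls[[cc]])
  calls <- cbind(data.frame(sample_id = rep(callset@sampleId, nrow(calls)),
                            stringsAsFactors = FALSE), calls)
  write.csv(calls, csvPath, row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(callset@members, auto_unbox = FALSE,
                              pretty = TRUE), membersPath)
  invisible(csvPath)
}
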