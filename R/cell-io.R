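#' @include AllClasses.R
NULL

## Fixed text dialect for every table: comma delimiter, decimal point,
## UTF-8, mandatory header.

#' Read a per-cell table from CSV
#'
#' Expects columns \code{cell_id}, \code{x_um}, \code{y_um}; every column
#' not in the reserved set (\code{compartment}, \code{primary_label}) is
#' treated as a marker unless \code{markerColumns} narrows the choice.
#' Continuous marker columns are accepted and preserved for
#' \code{\link{gateMarkers}}. Row order is preserved.
#'
#' @param path CSV file.
#' @param sampleId sample identifier; defaults to the file stem.
#' @param markerColumns optional explicit marker column names.
#' @return A \linkS4class{CellTable}.
#' @export
readCellTable <- function(path, sampleId = NULL, markerColumns = NULL) {
  if (!file.exists(path)) stopf("cell table not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("%s: missing required column '%s'", path, miss[1L])
  if (anyDuplicated(df$cell_id)) {
    dup <- df$cell_id[duplicated(df$cell_id)][1L]
    stopf("%s: duplicate cell_id '%s'", path, dup)
  }
  for (cc in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("%s: non-numeric coordinate in row %d, column '%s'",
            path, bad[1L], cc)
    df[[cc]] <- v
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  CellTable(df, sampleId = sampleId, markerNames = markerColumns)
}

#' Write a per-cell table to CSV
#'
#' Deterministic writer: fixed column order (\code{cell_id}, \code{x_um},
#' \code{y_um}, \code{compartment} if present, then markers, then any
#' phenotype columns), coordinates at fixed 3-decimal (nm) precision.
#'
#' @param table a \linkS4class{CellTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(table, path) {
  stopifnot(is(table, "CellTable"))
  df <- table@cells
  lead <- intersect(c("cell_id", "x_um", "y_um", "compartment"), colnames(df))
  rest <- c(intersect(table@markerNames, colnames(df)),
            setdiff(colnames(df), c(lead, table@markerNames)))
  df <- df[, c(lead, rest), drop = FALSE]
  df$x_um <- fmtUm(df$x_um)
  df$y_um <- fmtUm(df$y_um)
  for (cc in colnames(df))
    if (is.logical(df[[cc]])) df[[cc]] <- as.integer(df[[cc]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labeled region polygons from GeoJSON
#'
#' A FeatureCollection of Polygon features with a \code{label} property in
#' \{tumor, stroma, tissue\}; coordinates are interpreted as microns.
#' Invalid geometry (self-intersecting rings) and unknown labels are
#' rejected.
#'
#' @param path GeoJSON file.
#' @param sampleId sample identifier; defaults to the file stem.
#' @return A \linkS4class{RegionSet}.
#' @export
readRegions <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stopf("region file not found: %s", path)
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection"))
    stopf("%s: expected a GeoJSON FeatureCollection", path)
  polys <- lapply(doc$features, function(f) {
    lab <- f$properties$label
    if (is.null(lab) || !lab %in% REGION_LABELS)
      stopf("%s: unknown region label '%s'", path,
            if (is.null(lab)) "<missing>" else lab)
    if (!identical(f$geometry$type, "Polygon"))
      stopf("%s: only Polygon geometries are supported", path)
    ring <- f$geometry$coordinates[[1L]]
    co <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
    list(label = lab, coords = co)
  })
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  RegionSet(polys, sampleId = sampleId)
}

#' Write region polygons to GeoJSON
#'
#' Deterministic writer (fixed key order, fixed coordinate formatting);
#' rings are closed on output per the GeoJSON convention.
#'
#' @param regions a \linkS4class{RegionSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegions <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  features <- lapply(regions@polygons, function(p) {
    co <- rbind(p$coords, p$coords[1L, ])
    ring <- lapply(seq_len(nrow(co)), function(i)
      c(round(co[i, 1L], 3L), round(co[i, 2L], 3L)))
    list(type = "Feature",
         properties = list(label = p$label),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  doc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Label cells by region membership
#'
#' A cell is \code{tumor} if inside any tumor polygon (tumor takes
#' precedence over stroma on overlap, matching nests embedded in stroma),
#' else \code{stroma} if inside a stroma or tissue polygon, else
#' \code{unassigned}. Points on a polygon boundary count as inside.
#'
#' @param table a \linkS4class{CellTable}.
#' @param regions a non-empty \linkS4class{RegionSet}.
#' @return The \linkS4class{CellTable} with a \code{compartment} column.
#' @export
assignCompartments <- function(table, regions) {
  stopifnot(is(table, "CellTable"), is(regions, "RegionSet"))
  if (!length(regions@polygons)) stopf("regions must be non-empty")
  df <- table@cells
  inTumor <- rep(FALSE, nrow(df))
  inStroma <- rep(FALSE, nrow(df))
  for (p in regions@polygons) {
    hit <- pointsInPolygon(df$x_um, df$y_um, p$coords)
    if (p$label == "tumor") inTumor <- inTumor | hit
    else inStroma <- inStroma | hit
  }
  df$compartment <- ifelse(inTumor, "tumor",
                           ifelse(inStroma, "stroma", "unassigned"))
  table@cells <- df
  validObject(table)
  table
}

#' Read a clinical table from CSV
#'
#' Expects columns \code{sample_id}, \code{time_months} (> 0) and
#' \code{event} (0 censored / 1 event); further columns are covariates.
#'
#' @param path CSV file.
#' @return data.frame of survival records.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stopf("clinical table not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "time_months", "event"), colnames(df))
  if (length(miss)) stopf("%s: missing required column '%s'", path, miss[1L])
  if (!is.numeric(df$time_months) || any(!is.finite(df$time_months)) ||
      any(df$time_months <= 0))
    stopf("%s: time_months must be positive and finite", path)
  if (!all(df$event %in% c(0, 1)))
    stopf("%s: event must be 0 or 1", path)
  df
}

#' Read an expression matrix from CSV
#'
#' Genes as rows (first column gene symbol, header row of sample ids),
#' log-scale values.
#'
#' @param path CSV file.
#' @return Numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stopf("%s: duplicate gene symbol '%s'", path, genes[duplicated(genes)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stopf("%s: non-finite expression values", path)
  rownames(m) <- genes
  m
}

#' Write an expression matrix to CSV
#'
#' @param mat genes x samples matrix (or a SummarizedExperiment, first
#'   assay).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(mat, path) {
  if (is(mat, "SummarizedExperiment"))
    mat <- SummarizedExperiment::assay(mat)
  df <- data.frame(gene = rownames(mat), check.names = FALSE)
  df <- cbind(df, as.data.frame(signif(mat, 10L)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
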