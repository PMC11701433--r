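#' @import methods
NULL

RESERVED_CELL_COLUMNS <- c("cell_id", "x_um", "y_um", "compartment",
                           "primary_label")
COMPARTMENT_LEVELS <- c("tumor", "stroma", "unassigned")
REGION_LABELS <- c("tumor", "stroma", "tissue")

#' Marker vocabulary of the immunofluorescence panels
#'
#' The union of markers carried by the three staining panels the package
#' models: lymphocyte lineage and functional markers, follicular dendritic
#' cell markers, macrophage markers, the epithelial/tumor marker PanCK and
#' the immunogenic-cell-death marker CALR.
#'
#' @return Character vector of marker names.
#' @export
markerUniverse <- function() {
  c("CD4", "CD8", "CD20", "CD21", "CD23", "DC-LAMP", "GZMB", "PD1",
    "TCF1", "TIM-3", "FoxP3", "CXCR5", "CD68", "CD163", "PanCK", "CALR")
}

#' CellTable: per-cell coordinates and marker values for one sample
#'
#' One row per segmented cell with 2-D coordinates in microns (Cartesian,
#' origin bottom-left, y increasing upward), marker columns (binary after
#' gating, possibly continuous before), and an optional compartment label
#' (\code{tumor}, \code{stroma} or \code{unassigned}).
#'
#' @slot sampleId single sample identifier.
#' @slot cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, optional \code{compartment}, marker columns, and any
#'   phenotype columns added downstream.
#' @slot markerNames which columns of \code{cells} are markers (the marker
#'   vocabulary is open; tracked explicitly so phenotype columns added later
#'   are never mistaken for markers).
#' @export
setClass("CellTable",
  representation(sampleId = "character", cells = "data.frame",
                 markerNames = "character"))

setValidity("CellTable", function(object) {
  msg <- character(0)
  df <- object@cells
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  need <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    msg <- c(msg, paste0("missing required column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(df)) {
    if (anyDuplicated(df$cell_id)) {
      dup <- df$cell_id[duplicated(df$cell_id)][1L]
      msg <- c(msg, paste0("duplicate cell_id: '", dup, "'"))
    }
    if (!is.numeric(df$x_um) || !is.numeric(df$y_um) ||
        !all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
      msg <- c(msg, "coordinates x_um/y_um must be finite numerics")
    if ("compartment" %in% colnames(df) &&
        !all(df$compartment %in% COMPARTMENT_LEVELS))
      msg <- c(msg, paste0("compartment values must be one of: ",
                           paste(COMPARTMENT_LEVELS, collapse = ", ")))
  }
  bad <- setdiff(object@markerNames, colnames(df))
  if (length(bad))
    msg <- c(msg, paste0("markerNames not present as columns: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a CellTable
#'
#' @param cells data.frame with \code{cell_id}, \code{x_um}, \code{y_um} and
#'   marker columns.
#' @param sampleId sample identifier.
#' @param markerNames marker column names; by default every column that is
#'   not one of the reserved columns (\code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{compartment}, \code{primary_label}).
#' @return A \linkS4class{CellTable}.
#' @examples
#' ct <- CellTable(data.frame(cell_id = c("a", "b"), x_um = c(0, 10),
#'                            y_um = c(0, 0), CD8 = c(1, 0)), "s1")
#' nCells(ct)
#' @export
CellTable <- function(cells, sampleId = "sample", markerNames = NULL) {
  cells <- as.data.frame(cells)
  if (is.null(markerNames))
    markerNames <- setdiff(colnames(cells), RESERVED_CELL_COLUMNS)
  cells$cell_id <- as.character(cells$cell_id)
  rownames(cells) <- NULL
  new("CellTable", sampleId = sampleId, cells = cells,
      markerNames = markerNames)
}

#' RegionSet: labeled tissue polygons for one sample
#'
#' Polygons partitioning a slide into tumor nests and surrounding stroma
#' (label vocabulary: \code{tumor}, \code{stroma}, \code{tissue}).
#' Rings are stored open (closing vertex not repeated), coordinates in
#' microns.
#'
#' @slot sampleId sample identifier.
#' @slot polygons list of \code{list(label=, coords=)} with \code{coords} an
#'   n x 2 matrix.
#' @export
setClass("RegionSet",
  representation(sampleId = "character", polygons = "list"))

setValidity("RegionSet", function(object) {
  msg <- character(0)
  for (k in seq_along(object@polygons)) {
    p <- object@polygons[[k]]
    if (!is.list(p) || !all(c("label", "coords") %in% names(p))) {
      msg <- c(msg, sprintf("polygon %d lacks label/coords", k)); next
    }
    if (!p$label %in% REGION_LABELS)
      msg <- c(msg, sprintf("polygon %d: unknown label '%s'", k, p$label))
    co <- p$coords
    if (!is.matrix(co) || ncol(co) != 2L || nrow(co) < 3L ||
        !all(is.finite(co)))
      msg <- c(msg, sprintf("polygon %d: coords must be a finite n x 2 matrix with n >= 3", k))
    else if (ringSelfIntersects(co))
      msg <- c(msg, sprintf("polygon %d ('%s'): self-intersecting ring", k, p$label))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RegionSet
#'
#' @param polygons list of \code{list(label, coords)}; \code{coords} open
#'   rings (n x 2, microns). A closed ring (first vertex repeated at the end)
#'   is accepted and unclosed.
#' @param sampleId sample identifier.
#' @return A \linkS4class{RegionSet}.
#' @export
RegionSet <- function(polygons = list(), sampleId = "sample") {
  polygons <- lapply(polygons, function(p) {
    co <- as.matrix(p$coords)
    if (nrow(co) >= 2L && all(co[1L, ] == co[nrow(co), ]))
      co <- co[-nrow(co), , drop = FALSE]
    list(label = as.character(p$label), coords = unname(co))
  })
  new("RegionSet", sampleId = sampleId, polygons = polygons)
}

#' TLSSpec: one planted lymphoid aggregate for the slide simulator
#'
#' @slot center (x, y) disc center in microns.
#' @slot radiusUm disc radius (microns).
#' @slot nCells number of cells placed in the disc.
#' @slot composition named fractions over phenotype templates (must sum to
#'   1); see \code{\link{phenotypeTemplates}} for the template vocabulary.
#' @slot maturity one of \code{early}, \code{mature_primary},
#'   \code{mature_secondary}; constrains the FDC fractions (early aggregates
#'   carry no CD21+/CD23+ cells, primary-follicle aggregates at least one
#'   CD21+CD23- cell and no CD23+, secondary-follicle aggregates at least
#'   one CD21+CD23+ cell).
#' @slot packingSpacingUm target nearest-neighbor spacing of placed cells.
#' @export
setClass("TLSSpec",
  representation(center = "numeric", radiusUm = "numeric",
                 nCells = "integer", composition = "numeric",
                 maturity = "character", packingSpacingUm = "numeric"))

setValidity("TLSSpec", function(object) {
  msg <- character(0)
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    msg <- c(msg, "center must be finite (x, y)")
  if (object@radiusUm <= 0) msg <- c(msg, "radiusUm must be > 0")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@packingSpacingUm <= 0)
    msg <- c(msg, "packingSpacingUm must be > 0")
  comp <- object@composition
  if (is.null(names(comp)) || any(names(comp) == ""))
    msg <- c(msg, "composition must be named")
  if (any(comp < 0)) msg <- c(msg, "composition fractions must be >= 0")
  if (abs(sum(comp) - 1) > 1e-9)
    msg <- c(msg, "composition fractions must sum to 1")
  unknown <- setdiff(names(comp), names(phenotypeTemplates()))
  if (length(unknown))
    msg <- c(msg, paste0("unknown phenotype template(s): ",
                         paste(unknown, collapse = ", ")))
  mat <- object@maturity
  if (!mat %in% c("early", "mature_primary", "mature_secondary"))
    msg <- c(msg, "maturity must be early/mature_primary/mature_secondary")
  f21 <- if ("FDC21" %in% names(comp)) comp[["FDC21"]] else 0
  f2123 <- if ("FDC21_23" %in% names(comp)) comp[["FDC21_23"]] else 0
  if (identical(mat, "early") && (f21 > 0 || f2123 > 0))
    msg <- c(msg, "early maturity forbids FDC21/FDC21_23 fractions > 0")
  if (identical(mat, "mature_primary") && (f21 <= 0 || f2123 > 0))
    msg <- c(msg, "mature_primary requires FDC21 > 0 and FDC21_23 == 0")
  if (identical(mat, "mature_secondary") && f2123 <= 0)
    msg <- c(msg, "mature_secondary requires FDC21_23 > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TLSSpec
#'
#' @param center numeric (x, y) in microns.
#' @param radiusUm disc radius in microns.
#' @param nCells cells to place.
#' @param composition named fractions over phenotype templates summing to 1.
#' @param maturity \code{early}, \code{mature_primary} or
#'   \code{mature_secondary}.
#' @param packingSpacingUm target nearest-neighbor spacing (microns);
#'   keep it at or below the detector's contact distance so the planted
#'   aggregate is one connected component.
#' @return A \linkS4class{TLSSpec}.
#' @export
TLSSpec <- function(center, radiusUm, nCells, composition,
                    maturity = c("early", "mature_primary",
                                 "mature_secondary"),
                    packingSpacingUm = 8) {
  maturity <- match.arg(maturity)
  new("TLSSpec", center = as.numeric(center), radiusUm = as.numeric(radiusUm),
      nCells = as.integer(nCells), composition = composition,
      maturity = maturity, packingSpacingUm = as.numeric(packingSpacingUm))
}

#' SlideConfig: full configuration of one synthetic slide
#'
#' @slot fieldWidthUm,fieldHeightUm field extent in microns.
#' @slot backgroundRates named intensities (cells/mm^2) of homogeneous
#'   Poisson background processes, one per phenotype template.
#' @slot tumorNests data.frame with columns \code{x_um}, \code{y_um},
#'   \code{radius_um}, \code{rate} (PanCK+ cells/mm^2 inside the nest disc).
#' @slot tlsSpecs list of \linkS4class{TLSSpec}.
#' @slot markerFlipRate probability of independently flipping each marker
#'   flag of each cell.
#' @slot guardMarginUm background and nest cells are removed within this
#'   margin around every TLS disc, emulating the sharply demarcated boundary
#'   of real aggregates and making planted membership unambiguous.
#' @slot seed RNG seed; generation is a pure function of the config.
#' @export
setClass("SlideConfig",
  representation(fieldWidthUm = "numeric", fieldHeightUm = "numeric",
                 backgroundRates = "numeric", tumorNests = "data.frame",
                 tlsSpecs = "list", markerFlipRate = "numeric",
                 guardMarginUm = "numeric", seed = "integer"))

setValidity("SlideConfig", function(object) {
  msg <- character(0)
  w <- object@fieldWidthUm; h <- object@fieldHeightUm
  if (w <= 0 || h <= 0) msg <- c(msg, "field dimensions must be > 0")
  if (any(object@backgroundRates < 0))
    msg <- c(msg, "background rates must be >= 0")
  unknown <- setdiff(names(object@backgroundRates),
                     names(phenotypeTemplates()))
  if (length(unknown))
    msg <- c(msg, paste0("unknown background phenotype(s): ",
                         paste(unknown, collapse = ", ")))
  fr <- object@markerFlipRate
  if (fr < 0 || fr > 1) msg <- c(msg, "markerFlipRate must be in [0, 1]")
  if (object@guardMarginUm < 0) msg <- c(msg, "guardMarginUm must be >= 0")
  nests <- object@tumorNests
  if (nrow(nests)) {
    if (any(nests$radius_um <= 0)) msg <- c(msg, "nest radii must be > 0")
    if (any(nests$rate < 0)) msg <- c(msg, "nest rates must be >= 0")
    out <- nests$x_um - nests$radius_um < 0 | nests$x_um + nests$radius_um > w |
      nests$y_um - nests$radius_um < 0 | nests$y_um + nests$radius_um > h
    if (any(out))
      msg <- c(msg, sprintf("tumor nest %d lies outside the field",
                            which(out)[1L]))
  }
  specs <- object@tlsSpecs
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (!is(s, "TLSSpec")) { msg <- c(msg, "tlsSpecs must hold TLSSpec objects"); next }
    if (s@center[1L] - s@radiusUm < 0 || s@center[1L] + s@radiusUm > w ||
        s@center[2L] - s@radiusUm < 0 || s@center[2L] + s@radiusUm > h)
      msg <- c(msg, sprintf("TLS disc %d lies outside the field", k))
  }
  if (length(specs) > 1L) {
    for (a in seq_len(length(specs) - 1L)) for (b in (a + 1L):length(specs)) {
      sa <- specs[[a]]; sb <- specs[[b]]
      d <- sqrt(sum((sa@center - sb@center)^2))
      if (d < sa@radiusUm + sb@radiusUm)
        msg <- c(msg, sprintf("TLS discs %d and %d overlap (ground truth would be ambiguous)", a, b))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SlideConfig
#'
#' @param fieldWidthUm,fieldHeightUm field extent in microns.
#' @param backgroundRates named numeric, cells/mm^2 per phenotype template.
#' @param tumorNests data.frame (\code{x_um}, \code{y_um}, \code{radius_um},
#'   \code{rate}) or NULL.
#' @param tlsSpecs list of \code{\link{TLSSpec}} objects.
#' @param markerFlipRate per-cell per-marker flip probability in [0, 1].
#' @param guardMarginUm clearance ring around TLS discs (microns).
#' @param seed integer RNG seed.
#' @return A \linkS4class{SlideConfig}.
#' @export
SlideConfig <- function(fieldWidthUm = 2000, fieldHeightUm = 2000,
                        backgroundRates = numeric(0), tumorNests = NULL,
                        tlsSpecs = list(), markerFlipRate = 0,
                        guardMarginUm = 25, seed = 1) {
  if (is.null(tumorNests))
    tumorNests <- data.frame(x_um = numeric(0), y_um = numeric(0),
                             radius_um = numeric(0), rate = numeric(0))
  new("SlideConfig", fieldWidthUm = as.numeric(fieldWidthUm),
      fieldHeightUm = as.numeric(fieldHeightUm),
      backgroundRates = unlist(backgroundRates) %||% numeric(0),
      tumorNests = as.data.frame(tumorNests), tlsSpecs = tlsSpecs,
      markerFlipRate = as.numeric(markerFlipRate),
      guardMarginUm = as.numeric(guardMarginUm), seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CohortConfig: synthetic survival cohort with planted hazard ratios
#'
#' Event times are exponential with per-patient hazard
#' \code{baselineHazard * exp(sum(covariate * logHr))} (events/month);
#' censoring is independent exponential at \code{censorRate}.
#'
#' @slot nPatients cohort size (>= 2).
#' @slot baselineHazard events per month (> 0).
#' @slot logHr named log hazard ratios per covariate.
#' @slot censorRate censoring events per month (>= 0).
#' @slot covariates named list of generator specs:
#'   \code{list(dist="binary", p=)} or \code{list(dist="normal", mean=, sd=)}.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer", baselineHazard = "numeric",
                 logHr = "numeric", censorRate = "numeric",
                 covariates = "list", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censorRate < 0) msg <- c(msg, "censorRate must be >= 0")
  if (length(object@logHr) && is.null(names(object@logHr)))
    msg <- c(msg, "logHr must be named")
  miss <- setdiff(names(object@logHr), names(object@covariates))
  if (length(miss))
    msg <- c(msg, paste0("logHr names without a covariate generator: ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' @param nPatients cohort size.
#' @param baselineHazard baseline hazard, events/month.
#' @param logHr named numeric of log hazard ratios.
#' @param censorRate censoring rate, events/month.
#' @param covariates named list of covariate generator specs.
#' @param seed integer RNG seed.
#' @return A \linkS4class{CohortConfig}.
#' @export
CohortConfig <- function(nPatients, baselineHazard = 0.05,
                         logHr = numeric(0), censorRate = 0,
                         covariates = list(), seed = 1) {
  new("CohortConfig", nPatients = as.integer(nPatients),
      baselineHazard = as.numeric(baselineHazard),
      logHr = if (length(logHr)) unlist(logHr) else numeric(0),
      censorRate = as.numeric(censorRate), covariates = covariates,
      seed = as.integer(seed))
}

#' TLSCallSet: detected aggregates of one slide
#'
#' One row per connected component of the cell-contact graph, with its size,
#' Feret extent, B-cell fraction, lineage presence counts, centroid and
#' status (\code{rejected:<reason>}, \code{eTLS}, \code{mTLS_primary} or
#' \code{mTLS_secondary}).
#'
#' @slot sampleId sample identifier.
#' @slot calls data.frame of per-aggregate metrics and status.
#' @slot members named list (by \code{aggregate_id}) of member cell ids.
#' @slot params the \code{\link{detectorParams}} used.
#' @export
setClass("TLSCallSet",
  representation(sampleId = "character", calls = "data.frame",
                 members = "list", params = "list"))

setValidity("TLSCallSet", function(object) {
  msg <- character(0)
  need <- c("aggregate_id", "n_cells", "extent_um", "b_fraction", "n_cd4",
            "n_cd8", "n_cd21", "n_cd23", "n_cd21_cd23", "centroid_x",
            "centroid_y", "status")
  miss <- setdiff(need, colnames(object@calls))
  if (length(miss))
    msg <- c(msg, paste0("calls lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(object@calls) &&
      !setequal(names(object@members), object@calls$aggregate_id))
    msg <- c(msg, "members must be keyed by aggregate_id")
  if (length(msg)) msg else TRUE
})
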