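#' @include AllClasses.R
NULL

#' Accessors for spatialTLS classes
#'
#' \code{sampleId} returns the sample identifier; \code{cellData} the
#' per-cell data.frame; \code{markerNames} the marker columns; \code{nCells}
#' the number of cells; \code{regionPolygons} the polygon list;
#' \code{tlsCalls} the per-aggregate call table; \code{tlsMembers} the
#' member cell ids; \code{tlsSummary} per-sample counts of accepted calls.
#'
#' @param x a \linkS4class{CellTable}, \linkS4class{RegionSet} or
#'   \linkS4class{TLSCallSet}.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("regionPolygons", function(x) standardGeneric("regionPolygons"))
#' @rdname accessors
#' @export
setGeneric("tlsCalls", function(x) standardGeneric("tlsCalls"))
#' @rdname accessors
#' @export
setGeneric("tlsMembers", function(x) standardGeneric("tlsMembers"))
#' @rdname accessors
#' @export
setGeneric("tlsSummary", function(x) standardGeneric("tlsSummary"))

#' @rdname accessors
setMethod("sampleId", "CellTable", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "RegionSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "TLSCallSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("cellData", "CellTable", function(x) x@cells)
#' @rdname accessors
setMethod("markerNames", "CellTable", function(x) x@markerNames)
#' @rdname accessors
setMethod("nCells", "CellTable", function(x) nrow(x@cells))
#' @rdname accessors
setMethod("regionPolygons", "RegionSet", function(x) x@polygons)
#' @rdname accessors
setMethod("tlsCalls", "TLSCallSet", function(x) x@calls)
#' @rdname accessors
setMethod("tlsMembers", "TLSCallSet", function(x) x@members)

#' @rdname accessors
setMethod("tlsSummary", "TLSCallSet", function(x) {
  st <- x@calls$status
  nE <- sum(st == "eTLS")
  nM <- sum(st %in% c("mTLS_primary", "mTLS_secondary"))
  list(n_eTLS = nE, n_mTLS = nM, n_total_TLS = nE + nM)
})

setMethod("show", "CellTable", function(object) {
  cat("CellTable '", object@sampleId, "': ", nrow(object@cells),
      " cells, ", length(object@markerNames), " markers\n", sep = "")
  if (length(object@markerNames))
    cat("  markers: ", paste(head(object@markerNames, 8L), collapse = ", "),
        if (length(object@markerNames) > 8L) ", ..." else "", "\n", sep = "")
  if ("compartment" %in% colnames(object@cells)) {
    tb <- table(object@cells$compartment)
    cat("  compartments: ",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "RegionSet", function(object) {
  labs <- vapply(object@polygons, `[[`, character(1L), "label")
  cat("RegionSet '", object@sampleId, "': ", length(object@polygons),
      " polygon(s)", sep = "")
  if (length(labs)) {
    tb <- table(labs)
    cat(" (", paste(names(tb), tb, sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

setMethod("show", "TLSCallSet", function(object) {
  s <- tlsSummary(object)
  cat("TLSCallSet '", object@sampleId, "': ", nrow(object@calls),
      " aggregate(s); eTLS=", s$n_eTLS, ", mTLS=", s$n_mTLS, "\n", sep = "")
})

setMethod("show", "SlideConfig", function(object) {
  cat("SlideConfig: ", object@fieldWidthUm, " x ", object@fieldHeightUm,
      " um field, ", length(object@tlsSpecs), " TLS spec(s), ",
      nrow(object@tumorNests), " tumor nest(s), flip rate ",
      object@markerFlipRate, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: n=", object@nPatients, ", baseline hazard ",
      object@baselineHazard, "/month, censor rate ", object@censorRate,
      ", covariates: ",
      paste(names(object@covariates), collapse = ", "), "\n", sep = "")
})
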