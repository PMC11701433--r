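#' @include AllClasses.R
NULL

#' Built-in metagene signatures
#'
#' \code{ER_stress}: the three-gene endoplasmic-reticulum stress module
#' (DDIT3/CHOP, HSPA5/BiP, HSP90B1) that tracks immunogenic cell death in
#' tumors. \code{TLS_chemokine}: the twelve-chemokine module associated
#' with tertiary lymphoid structure formation (CCL2, CCL3, CCL4, CCL5,
#' CCL8, CCL18, CCL19, CCL21, CXCL9, CXCL10, CXCL11, CXCL13).
#'
#' @return Named list of gene-symbol vectors.
#' @export
builtinSignatures <- function() {
  list(
    ER_stress = c("DDIT3", "HSPA5", "HSP90B1"),
    TLS_chemokine = c("CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18",
                      "CCL19", "CCL21", "CXCL9", "CXCL10", "CXCL11",
                      "CXCL13")
  )
}

#' Load user signatures from YAML
#'
#' Top-level mapping of signature name to a sequence of gene symbols
#' (e.g. B-cell subtype lists supplied by the user).
#'
#' @param path YAML file.
#' @return Named list of gene-symbol vectors.
#' @export
loadSignatures <- function(path) {
  if (!file.exists(path)) stopf("signature file not found: %s", path)
  doc <- yaml::read_yaml(path)
  sigs <- lapply(doc, function(g) as.character(unlist(g)))
  for (nm in names(sigs))
    if (anyDuplicated(sigs[[nm]]))
      stopf("signature '%s' has duplicate gene symbol '%s'", nm,
            sigs[[nm]][duplicated(sigs[[nm]])][1L])
  sigs
}

#' Score a metagene signature on an expression matrix
#'
#' Each present signature gene row is z-scored across samples (mean 0,
#' sd 1; constant rows are dropped with a warning); the sample score is
#' the mean of the z-scores over the genes used. A one-gene signature
#' score therefore equals that gene's z-scored value. Genes absent from
#' the matrix are dropped, not imputed; coverage is reported.
#'
#' @param mat genes x samples numeric matrix (log scale) or a
#'   SummarizedExperiment (first assay).
#' @param genes signature gene symbols.
#' @param name signature name carried into the output.
#' @return data.frame with \code{sample_id}, \code{score} and attributes
#'   \code{signature}, \code{coverage} (present / listed genes),
#'   \code{genes_used}, \code{genes_missing}.
#' @export
scoreSignature <- function(mat, genes, name = "signature") {
  if (is(mat, "SummarizedExperiment"))
    mat <- SummarizedExperiment::assay(mat)
  if (anyDuplicated(rownames(mat))) stopf("duplicate gene symbols in matrix")
  present <- intersect(genes, rownames(mat))
  missing <- setdiff(genes, rownames(mat))
  if (!length(present))
    stopf("no signature gene present in the matrix: %s",
          paste(genes, collapse = ", "))
  sub <- mat[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warnf("dropping constant gene row(s): %s",
          paste(present[flat], collapse = ", "))
    sub <- sub[!flat, , drop = FALSE]
    present <- present[!flat]
    if (!nrow(sub)) stopf("all signature genes constant across samples")
  }
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  score <- colMeans(z)
  out <- data.frame(sample_id = colnames(mat) %||%
                      sprintf("s%03d", seq_len(ncol(mat))),
                    score = unname(score), stringsAsFactors = FALSE)
  attr(out, "signature") <- name
  attr(out, "coverage") <- length(present) / length(genes)
  attr(out, "genes_used") <- present
  attr(out, "genes_missing") <- missing
  out
}
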