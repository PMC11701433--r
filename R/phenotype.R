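#' @include AllClasses.R
NULL

#' Marker templates of the simulated phenotypes
#'
#' Maps each phenotype template name used by the slide simulator to the
#' marker flags set on generated cells (all other markers are 0). Tumor
#' cells are PanCK+; follicular helper T cells (TFH) carry
#' CD4+CXCR5+PD1+; follicular dendritic cells carry CD21 (primary
#' follicle) or CD21+CD23 (secondary follicle); "other" has no marker.
#'
#' @return Named list of character vectors of positive markers.
#' @export
phenotypeTemplates <- function() {
  list(
    Tumor = "PanCK",
    CD8T = "CD8",
    PD1_CD8T = c("CD8", "PD1"),
    TCF1_PD1_CD8T = c("CD8", "PD1", "TCF1"),
    TIM3_PD1_CD8T = c("CD8", "PD1", "TIM-3"),
    GZMB_CD8T = c("CD8", "GZMB"),
    CD4T = "CD4",
    TFH = c("CD4", "CXCR5", "PD1"),
    Treg = c("CD4", "FoxP3"),
    Bcell = "CD20",
    DC = "DC-LAMP",
    TAM = "CD68",
    M2TAM = c("CD68", "CD163"),
    FDC21 = "CD21",
    FDC21_23 = c("CD21", "CD23"),
    other = character(0)
  )
}

#' Define a phenotype gating rule
#'
#' A cell matches the rule when every marker in \code{requirePos} is 1 and
#' every marker in \code{requireNeg} is 0. Rules are multilabel: a cell may
#' match several rules; the \code{priority} (lower = earlier) only decides
#' the single reporting label.
#'
#' @param name rule name (unique within a rule set).
#' @param requirePos markers that must be positive.
#' @param requireNeg markers that must be negative.
#' @param priority integer; lower numbers win the primary label.
#' @return A \code{PhenotypeRule} (classed list).
#' @export
phenotypeRule <- function(name, requirePos, requireNeg = character(0),
                          priority = 100L) {
  if (length(intersect(requirePos, requireNeg)))
    stopf("rule '%s': markers cannot be both required-positive and required-negative (%s)",
          name, paste(intersect(requirePos, requireNeg), collapse = ", "))
  structure(list(name = as.character(name),
                 require_pos = as.character(requirePos),
                 require_neg = as.character(requireNeg),
                 priority = as.integer(priority)),
            class = "PhenotypeRule")
}

#' The default phenotype rule set
#'
#' The immune populations quantified throughout the package: tumor cells
#' (PanCK+); the CD8 lineage including PD1+ and the progenitor-exhausted
#' (TCF1+PD1+CD8+) vs terminally exhausted (TIM-3+PD1+CD8+) states and
#' GZMB+ effectors; the CD4 lineage including CXCR5+PD1+FoxP3- follicular
#' helper T cells and FoxP3+ Tregs; CD20+ B cells; DC-LAMP+ dendritic
#' cells; CD68+ macrophages and their CD163+ M2-like subset; and CD21+
#' (+/- CD23+) follicular dendritic cells. Populations overlap by design
#' (every TCF1+PD1+CD8+ cell is also a PD1+CD8+ and a CD8+ cell); the CD8+
#' rule does not exclude CD4+CD8+ double positives. Priorities order the
#' primary reporting label from the most specific state to the lineage
#' gate.
#'
#' @return List of \code{\link{phenotypeRule}} objects.
#' @export
defaultRules <- function() {
  list(
    phenotypeRule("Tumor", "PanCK", priority = 10L),
    phenotypeRule("TCF1_PD1_CD8T", c("CD8", "PD1", "TCF1"), priority = 20L),
    phenotypeRule("TIM3_PD1_CD8T", c("CD8", "PD1", "TIM-3"), priority = 21L),
    phenotypeRule("GZMB_CD8T", c("CD8", "GZMB"), priority = 22L),
    phenotypeRule("PD1_CD8T", c("CD8", "PD1"), priority = 23L),
    phenotypeRule("CD8T", "CD8", priority = 24L),
    phenotypeRule("TFH", c("CD4", "CXCR5", "PD1"), requireNeg = "FoxP3",
                  priority = 30L),
    phenotypeRule("Treg", c("CD4", "FoxP3"), priority = 31L),
    phenotypeRule("CD4T", "CD4", priority = 32L),
    phenotypeRule("Bcell", "CD20", priority = 40L),
    phenotypeRule("DC", "DC-LAMP", priority = 50L),
    phenotypeRule("M2TAM", c("CD68", "CD163"), priority = 60L),
    phenotypeRule("TAM", "CD68", priority = 61L),
    phenotypeRule("FDC21_23", c("CD21", "CD23"), priority = 70L),
    phenotypeRule("FDC21", "CD21", priority = 71L)
  )
}

#' Load phenotype rules from YAML
#'
#' Expects a top-level \code{rules:} sequence of mappings with keys
#' \code{name}, \code{require_pos}, optional \code{require_neg} and
#' \code{priority}.
#'
#' @param path YAML file.
#' @return List of \code{\link{phenotypeRule}} objects.
#' @export
loadRules <- function(path) {
  if (!file.exists(path)) stopf("rule file not found: %s", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$rules %||% doc
  rules <- lapply(entries, function(e)
    phenotypeRule(e$name, unlist(e$require_pos),
                  unlist(e$require_neg) %||% character(0),
                  e$priority %||% 100L))
  nm <- vapply(rules, `[[`, character(1L), "name")
  if (anyDuplicated(nm))
    stopf("duplicate rule name: %s", nm[duplicated(nm)][1L])
  rules
}

#' Threshold continuous marker intensities into binary flags
#'
#' Marker value becomes 1 iff intensity >= cutoff (inclusive at the
#' boundary). Markers without a threshold pass through unchanged (they must
#' already be binary to be used downstream).
#'
#' @param table a \linkS4class{CellTable}.
#' @param thresholds named numeric, marker -> cutoff.
#' @return The gated \linkS4class{CellTable}.
#' @export
gateMarkers <- function(table, thresholds) {
  stopifnot(is(table, "CellTable"))
  df <- table@cells
  for (mk in names(thresholds)) {
    if (!mk %in% colnames(df))
      stopf("threshold given for missing marker column '%s'", mk)
    if (!is.numeric(df[[mk]]))
      stopf("marker column '%s' is not numeric", mk)
    df[[mk]] <- as.integer(df[[mk]] >= thresholds[[mk]])
  }
  table@cells <- df
  table
}

ruleMatches <- function(df, rule) {
  miss <- setdiff(c(rule$require_pos, rule$require_neg), colnames(df))
  if (length(miss))
    stopf("rule '%s' references unknown marker column '%s'",
          rule$name, miss[1L])
  ok <- rep(TRUE, nrow(df))
  for (mk in rule$require_pos) ok <- ok & df[[mk]] == 1
  for (mk in rule$require_neg) ok <- ok & df[[mk]] == 0
  ok
}

#' Assign phenotype labels from gated markers
#'
#' Adds one logical column per rule (multilabel; populations may overlap)
#' plus a single \code{primary_label} column holding the name of the
#' matching rule with the lowest priority number, or \code{"other"}.
#'
#' @param table gated \linkS4class{CellTable} (all rule markers binary).
#' @param rules list of \code{\link{phenotypeRule}}; default
#'   \code{\link{defaultRules}()}.
#' @return The annotated \linkS4class{CellTable}.
#' @export
assignPhenotypes <- function(table, rules = defaultRules()) {
  stopifnot(is(table, "CellTable"))
  df <- table@cells
  nm <- vapply(rules, `[[`, character(1L), "name")
  if (anyDuplicated(nm))
    stopf("duplicate rule name: %s", nm[duplicated(nm)][1L])
  for (mk in unique(unlist(lapply(rules, function(r)
    c(r$require_pos, r$require_neg))))) {
    if (!mk %in% colnames(df))
      stopf("rule marker '%s' is not a column of the cell table", mk)
    if (!isBinary01(df[[mk]]))
      stopf("marker '%s' is not binary; gate it first", mk)
  }
  match_mat <- matrix(FALSE, nrow(df), length(rules),
                      dimnames = list(NULL, nm))
  for (k in seq_along(rules)) match_mat[, k] <- ruleMatches(df, rules[[k]])
  prio <- vapply(rules, `[[`, integer(1L), "priority")
  ord <- order(prio, seq_along(rules))
  primary <- rep("other", nrow(df))
  for (k in rev(ord)) primary[match_mat[, k]] <- nm[k]
  for (k in seq_along(rules)) df[[nm[k]]] <- match_mat[, k]
  df$primary_label <- primary
  table@cells <- df
  table
}

#' Per-label cell counts of a phenotyped table
#'
#' @param table a \linkS4class{CellTable} processed by
#'   \code{\link{assignPhenotypes}}.
#' @param rules the rule set used (default rules otherwise).
#' @return data.frame with columns \code{phenotype} and \code{count}
#'   (multilabel counts), plus an attribute \code{primary} with the
#'   primary-label table.
#' @export
phenotypeSummary <- function(table, rules = defaultRules()) {
  df <- table@cells
  nm <- vapply(rules, `[[`, character(1L), "name")
  miss <- setdiff(nm, colnames(df))
  if (length(miss))
    stopf("phenotype column '%s' missing; run assignPhenotypes first", miss[1L])
  out <- data.frame(phenotype = nm,
                    count = vapply(nm, function(k) sum(df[[k]]), numeric(1L)),
                    row.names = NULL)
  attr(out, "primary") <- table(factor(df$primary_label,
                                       levels = c(nm, "other")))
  out
}
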