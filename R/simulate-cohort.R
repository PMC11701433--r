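#' @include AllClasses.R
NULL

drawCovariate <- function(spec, n) {
  dist <- spec$dist %||% "normal"
  switch(dist,
    binary = rbinom(n, 1L, spec$p %||% 0.5),
    normal = rnorm(n, spec$mean %||% 0, spec$sd %||% 1),
    stopf("unknown covariate distribution '%s'", dist))
}

#' Simulate a survival cohort with planted hazard ratios
#'
#' Event times are exponential with per-patient hazard
#' \code{baselineHazard * exp(sum(beta * x))}; censoring is independent
#' exponential at \code{censorRate} (none when 0). Observed time is the
#' minimum of the two, the event flag 1 iff the event came first.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return data.frame with \code{sample_id}, \code{time_months},
#'   \code{event} and one column per covariate.
#' @examples
#' cfg <- CohortConfig(100, baselineHazard = 0.05,
#'                     logHr = c(grp = log(2)),
#'                     covariates = list(grp = list(dist = "binary", p = 0.5)))
#' head(simulateCohort(cfg))
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nPatients
    covs <- lapply(config@covariates, drawCovariate, n = n)
    lp <- rep(0, n)
    for (nm in names(config@logHr)) lp <- lp + config@logHr[[nm]] * covs[[nm]]
    hazard <- config@baselineHazard * exp(lp)
    if (any(!is.finite(hazard)))
      stopf("non-finite hazard for record %d", which(!is.finite(hazard))[1L])
    tev <- rexp(n, rate = hazard)
    tcn <- if (config@censorRate > 0) rexp(n, rate = config@censorRate)
           else rep(Inf, n)
    out <- data.frame(sample_id = sprintf("p%04d", seq_len(n)),
                      time_months = pmin(tev, tcn),
                      event = as.integer(tev <= tcn))
    for (nm in names(covs)) out[[nm]] <- covs[[nm]]
    out
  })
}

#' Simulate a two-group log-scale expression matrix
#'
#' Signature genes are Normal(0, 1) in group A and Normal(shift, 1) in
#' group B; noise genes are Normal(0, 1) in both groups.
#'
#' @param nPerGroup samples per group (>= 2).
#' @param signatureGenes character vector of signature gene symbols.
#' @param shift group-B mean shift of the signature genes (log units).
#' @param nNoiseGenes number of unshifted noise genes.
#' @param seed integer RNG seed.
#' @return A \code{SummarizedExperiment} (assay \code{logexpr}, genes x
#'   samples) with a \code{group} column ("A"/"B") in its colData.
#' @export
simulateExpression <- function(nPerGroup, signatureGenes, shift,
                               nNoiseGenes = 100L, seed = 1L) {
  if (nPerGroup < 2L) stopf("nPerGroup must be >= 2")
  if (!is.finite(shift)) stopf("shift must be finite")
  if (anyDuplicated(signatureGenes))
    stopf("duplicate gene name: %s",
          signatureGenes[duplicated(signatureGenes)][1L])
  noise <- if (nNoiseGenes > 0L) sprintf("NOISE_%04d", seq_len(nNoiseGenes))
           else character(0)
  genes <- c(signatureGenes, noise)
  if (anyDuplicated(genes))
    stopf("duplicate gene name: %s", genes[duplicated(genes)][1L])
  withSeed(seed, {
    ns <- 2L * nPerGroup
    m <- matrix(rnorm(length(genes) * ns), length(genes), ns,
                dimnames = list(genes,
                                c(sprintf("A_%03d", seq_len(nPerGroup)),
                                  sprintf("B_%03d", seq_len(nPerGroup)))))
    grp <- rep(c("A", "B"), each = nPerGroup)
    if (length(signatureGenes))
      m[signatureGenes, grp == "B"] <-
        m[signatureGenes, grp == "B"] + shift
    SummarizedExperiment::SummarizedExperiment(
      assays = list(logexpr = m),
      colData = S4Vectors::DataFrame(group = grp,
                                     row.names = colnames(m)))
  })
}
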