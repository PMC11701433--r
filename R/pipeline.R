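#' @include AllClasses.R
NULL

detectorParamsFromList <- function(d) {
  if (is.null(d)) return(detectorParams())
  detectorParams(
    contactDistanceUm = d$contact_distance_um %||% 13.0,
    minCells = d$min_cells %||% 51L,
    minExtentUm = d$min_extent_um %||% 250.0,
    bMajorityFraction = d$b_majority_fraction %||% 0.5,
    requireCd4 = d$require_cd4 %||% TRUE,
    requireCd8 = d$require_cd8 %||% TRUE,
    maturityRule = d$maturity_rule %||% "follicle")
}

stageGuard <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

writeTidyCsv <- function(df, path, numericCols = NULL) {
  for (cc in numericCols)
    if (cc %in% colnames(df)) df[[cc]] <- sprintf("%.6f", df[[cc]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full spatial immune-contexture pipeline
#'
#' Executes gate, phenotype, compartments, TLS detection, densities,
#' contacts, and (when expression / clinical inputs are configured)
#' signature scoring and median-stratified survival analysis, writing
#' tidy CSV outputs and a run-manifest JSON (config echo, package
#' version, per-stage row counts and wall times) under \code{outdir}.
#' Reruns with an identical config reproduce identical outputs (the
#' manifest's wall times aside).
#'
#' @param config path to a YAML run config, or an equivalent list. Keys:
#'   \code{samples} (list of \code{sample_id}/\code{cells}/optional
#'   \code{regions}), optional \code{thresholds}, \code{rules},
#'   \code{detector}, \code{contacts} (\code{target}, \code{queries},
#'   \code{bin_edges}), \code{expression}, \code{signatures},
#'   \code{clinical}, \code{survival} (\code{stratify_by},
#'   \code{covariates}), \code{seed}. Relative paths resolve against the
#'   config file's directory.
#' @param outdir output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir) {
  t0 <- proc.time()[["elapsed"]]
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(base, p)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "spatialTLS",
                   version = as.character(utils::packageVersion("spatialTLS")),
                   config = config, stages = list())
  timeds <- function(stage, expr) {
    st <- proc.time()[["elapsed"]]
    n <- stageGuard(stage, expr)
    manifest$stages[[stage]] <<- list(rows = n,
                                      wall_s = round(proc.time()[["elapsed"]] - st, 3L))
    n
  }
  if (is.null(config$samples) || !length(config$samples))
    stopf("config must list at least one sample")
  for (s in config$samples) {
    p <- resolve(s$cells)
    if (!file.exists(p)) stopf("input file not found: %s", s$cells)
    if (!is.null(s$regions) && !file.exists(resolve(s$regions)))
      stopf("input file not found: %s", s$regions)
  }
  for (key in c("expression", "clinical", "rules", "signatures"))
    if (!is.null(config[[key]]) && !file.exists(resolve(config[[key]])))
      stopf("input file not found: %s", config[[key]])

  ## gate
  tables <- NULL
  timeds("gate", {
    tables <- lapply(config$samples, function(s) {
      tab <- readCellTable(resolve(s$cells), sampleId = s$sample_id)
      if (length(config$thresholds))
        tab <- gateMarkers(tab, unlist(config$thresholds))
      tab
    })
    names(tables) <- vapply(config$samples, `[[`, character(1L),
                             "sample_id")
    sum(vapply(tables, nCells, numeric(1L)))
  })
  rules <- if (!is.null(config$rules)) loadRules(resolve(config$rules))
           else defaultRules()

  ## phenotype
  timeds("phenotype", {
    tables <- lapply(tables, assignPhenotypes, rules = rules)
    counts <- do.call(rbind, lapply(tables, function(tab)
      cbind(sample_id = sampleId(tab), phenotypeSummary(tab, rules))))
    writeTidyCsv(counts, file.path(outdir, "phenotype_counts.csv"))
    nrow(counts)
  })

  ## compartments
  regionsBySample <- list()
  timeds("compartments", {
    nAssigned <- 0
    for (s in config$samples) {
      if (is.null(s$regions)) next
      rg <- readRegions(resolve(s$regions), sampleId = s$sample_id)
      regionsBySample[[s$sample_id]] <- rg
      tables[[s$sample_id]] <- assignCompartments(tables[[s$sample_id]], rg)
      nAssigned <- nAssigned + nCells(tables[[s$sample_id]])
    }
    nAssigned
  })

  ## TLS detection
  params <- detectorParamsFromList(config$detector)
  callsets <- NULL
  timeds("tls", {
    callsets <- lapply(tables, detectTLS, params = params)
    allCalls <- do.call(rbind, lapply(callsets, function(cs) {
      df <- tlsCalls(cs)
      cbind(data.frame(sample_id = rep(sampleId(cs), nrow(df)),
                       stringsAsFactors = FALSE), df)
    }))
    writeTidyCsv(allCalls, file.path(outdir, "tls_calls.csv"),
                 c("extent_um", "b_fraction", "centroid_x", "centroid_y"))
    members <- lapply(callsets, tlsMembers)
    writeLines(jsonlite::toJSON(members, auto_unbox = FALSE, pretty = TRUE),
               file.path(outdir, "tls_members.json"))
    summ <- do.call(rbind, lapply(callsets, function(cs)
      data.frame(sample_id = sampleId(cs), as.data.frame(tlsSummary(cs)))))
    writeTidyCsv(summ, file.path(outdir, "tls_summary.csv"))
    nrow(allCalls)
  })

  ## densities
  timeds("densities", {
    dens <- do.call(rbind, lapply(names(tables), function(sid)
      computeDensities(tables[[sid]], regionsBySample[[sid]])))
    writeTidyCsv(dens, file.path(outdir, "densities.csv"),
                 c("area_mm2", "density_cells_per_mm2"))
    nrow(dens)
  })

  ## contacts
  timeds("contacts", {
    cc <- config$contacts %||% list()
    target <- cc$target %||% "Tumor"
    queries <- unlist(cc$queries) %||%
      c("TCF1_PD1_CD8T", "TIM3_PD1_CD8T")
    edges <- unlist(cc$bin_edges) %||% c(0, 10, 20, 30)
    rows <- list()
    for (sid in names(tables)) for (q in queries) {
      pr <- contactProfile(tables[[sid]], target, q, edges)
      rows[[paste(sid, q)]] <- cbind(
        data.frame(sample_id = sid, target = target, query = q,
                   stringsAsFactors = FALSE),
        pr$bins,
        data.frame(n_targets = pr$n_targets, n_queries = pr$n_queries,
                   close_fraction = pr$close_fraction))
    }
    contacts <- do.call(rbind, rows)
    rownames(contacts) <- NULL
    writeTidyCsv(contacts, file.path(outdir, "contacts.csv"),
                 "close_fraction")
    nrow(contacts)
  })

  ## signatures
  timeds("signatures", {
    if (is.null(config$expression)) 0 else {
      mat <- readExpression(resolve(config$expression))
      sigs <- builtinSignatures()
      if (!is.null(config$signatures))
        sigs <- c(sigs, loadSignatures(resolve(config$signatures)))
      rows <- list()
      for (nm in names(sigs)) {
        ## a signature none of whose genes were measured is skipped
        sc <- tryCatch(suppressWarnings(scoreSignature(mat, sigs[[nm]], nm)),
                       error = function(e) NULL)
        if (is.null(sc)) next
        rows[[nm]] <- cbind(data.frame(signature = nm,
                                       stringsAsFactors = FALSE), sc)
      }
      scores <- do.call(rbind, rows)
      rownames(scores) <- NULL
      writeTidyCsv(scores, file.path(outdir, "signature_scores.csv"),
                   "score")
      nrow(scores)
    }
  })

  ## survival
  timeds("survival", {
    if (is.null(config$clinical)) 0 else {
      clin <- readClinical(resolve(config$clinical))
      sv <- config$survival %||% list()
      rows <- 0
      if (!is.null(sv$stratify_by)) {
        col <- sv$stratify_by
        if (!col %in% colnames(clin))
          stopf("stratify_by column '%s' not in clinical table", col)
        vals <- stats::setNames(clin[[col]], clin$sample_id)
        strat <- medianStratify(vals)
        clin$stratum <- unname(strat[clin$sample_id])
        kmRows <- list()
        for (g in sort(unique(clin$stratum))) {
          km <- kmEstimate(clin[clin$stratum == g, ])
          kmRows[[g]] <- data.frame(stratum = g, time = km$time,
                                    n_risk = km$n_risk,
                                    n_event = km$n_event,
                                    n_censor = km$n_censor, surv = km$surv)
        }
        kmDf <- do.call(rbind, kmRows)
        rownames(kmDf) <- NULL
        writeTidyCsv(kmDf, file.path(outdir, "km_curves.csv"),
                     c("time", "surv"))
        lr <- logrankTest(clin, "stratum")
        writeTidyCsv(data.frame(test = "logrank", stratify_by = col,
                                chi2 = sprintf("%.6f", lr$chi2),
                                df = lr$df, p = sprintf("%.6g", lr$p)),
                     file.path(outdir, "survival_tests.csv"))
        rows <- rows + nrow(kmDf) + 1L
      }
      covs <- unlist(sv$covariates) %||% character(0)
      if (length(covs)) {
        cx <- do.call(rbind, lapply(covs, function(cv) {
          f <- coxUnivariate(clin, cv)
          data.frame(covariate = f$covariate,
                     log_hr = sprintf("%.6f", f$log_hr),
                     se = sprintf("%.6f", f$se),
                     hr = sprintf("%.6f", f$hr),
                     ci95_lo = sprintf("%.6f", f$ci95_lo),
                     ci95_hi = sprintf("%.6f", f$ci95_hi),
                     p = sprintf("%.6g", f$p))
        }))
        writeTidyCsv(cx, file.path(outdir, "cox_fits.csv"))
        rows <- rows + nrow(cx)
      }
      rows
    }
  })

  manifest$total_wall_s <- round(proc.time()[["elapsed"]] - t0, 3L)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outdir, "manifest.json"))
  invisible(manifest)
}

demoSlideConfigs <- function(seed) {
  mk <- function(...) list(...)
  bg <- c(CD8T = 50, CD4T = 50, Bcell = 30, TCF1_PD1_CD8T = 20,
          TIM3_PD1_CD8T = 20, TFH = 10, M2TAM = 15, DC = 10, Tumor = 15,
          other = 40)
  comp <- function(extra) {
    base <- c(Bcell = 0.60, CD4T = 0.14, CD8T = 0.12, TFH = 0.05,
              other = 0.09)
    base[names(extra)] <- extra
    base / sum(base)
  }
  nest <- function(x, y, r, rate = 1500)
    data.frame(x_um = x, y_um = y, radius_um = r, rate = rate)
  list(
    s1 = SlideConfig(1500, 1500, bg, tlsSpecs = list(
      TLSSpec(c(350, 350), 140, 320, comp(c(FDC21 = 0.02, FDC21_23 = 0.02)),
              "mature_secondary"),
      TLSSpec(c(1100, 1100), 130, 180, comp(c()), "early")),
      seed = seed + 11L),
    s2 = SlideConfig(1500, 1500, bg, tlsSpecs = list(
      TLSSpec(c(750, 750), 135, 260, comp(c(FDC21 = 0.03)),
              "mature_primary")),
      seed = seed + 12L),
    s3 = SlideConfig(1500, 1500, bg,
      tumorNests = nest(1100, 400, 180),
      tlsSpecs = list(
        TLSSpec(c(400, 1050), 140, 300,
                comp(c(FDC21 = 0.02, FDC21_23 = 0.02)), "mature_secondary")),
      seed = seed + 13L),
    s4 = SlideConfig(1500, 1500, bg, tumorNests = nest(750, 750, 200),
                     seed = seed + 14L),
    s5 = SlideConfig(1500, 1500, bg, seed = seed + 15L),
    s6 = SlideConfig(1500, 1500, bg * 0.5, seed = seed + 16L)
  )
}

demoRegions <- function(sid, field = 1500) {
  sq <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  polys <- list(list(label = "tissue", coords = sq(0, 0, field, field)))
  if (sid == "s3")
    polys <- c(polys, list(list(label = "tumor",
                                coords = sq(900, 200, 1300, 600))))
  if (sid == "s4")
    polys <- c(polys, list(list(label = "tumor",
                                coords = sq(530, 530, 970, 970))))
  RegionSet(polys, sampleId = sid)
}

#' Generate the packaged synthetic demo dataset
#'
#' Writes a small six-sample cohort exercising every pipeline stage:
#' cell tables (three samples carrying planted mature TLS, one also an
#' early TLS; two tumor nests with region polygons; two TLS-free
#' samples), planted-truth JSONs, a clinical table from
#' \code{\link{simulateCohort}}, a two-group expression matrix with the
#' TLS chemokine signature shifted, and a ready-to-run pipeline config.
#' Deterministic in \code{seed}.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return Path to the written config YAML, invisibly.
#' @export
simulateDemo <- function(dir, seed = 1L) {
  seed <- as.integer(seed)
  dir.create(file.path(dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  cfgs <- demoSlideConfigs(seed)
  sampleEntries <- list()
  for (sid in names(cfgs)) {
    sl <- simulateSlide(cfgs[[sid]])
    tab <- sl$table
    tab@sampleId <- sid
    cellsPath <- file.path("samples", paste0(sid, "_cells.csv"))
    writeCellTable(tab, file.path(dir, cellsPath))
    writeLines(jsonlite::toJSON(sl$truth, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "samples", paste0(sid, "_truth.json")))
    entry <- list(sample_id = sid, cells = cellsPath)
    if (sid %in% c("s3", "s4")) {
      rgPath <- file.path("samples", paste0(sid, "_regions.geojson"))
      writeRegions(demoRegions(sid), file.path(dir, rgPath))
      entry$regions <- rgPath
    }
    sampleEntries[[sid]] <- entry
  }
  clin <- simulateCohort(CohortConfig(
    nPatients = 40L, baselineHazard = 0.04,
    logHr = c(score = log(2) / 2), censorRate = 0.01,
    covariates = list(score = list(dist = "normal", mean = 0, sd = 1)),
    seed = seed + 21L))
  clin$time_months <- round(clin$time_months, 4L)
  clin$score <- round(clin$score, 4L)
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE,
            quote = FALSE)
  expr <- simulateExpression(20L, builtinSignatures()$TLS_chemokine,
                             shift = 1.5, nNoiseGenes = 60L,
                             seed = seed + 22L)
  writeExpression(expr, file.path(dir, "expression.csv"))
  config <- list(samples = unname(sampleEntries),
                 detector = list(contact_distance_um = 13.0),
                 contacts = list(target = "Tumor",
                                 queries = list("TCF1_PD1_CD8T",
                                                "TIM3_PD1_CD8T"),
                                 bin_edges = list(0, 10, 20, 30)),
                 expression = "expression.csv",
                 clinical = "clinical.csv",
                 survival = list(stratify_by = "score",
                                 covariates = list("score")),
                 seed = seed)
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  invisible(cfgPath)
}
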