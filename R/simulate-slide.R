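#' @include AllClasses.R phenotype.R
NULL

## Deterministic integer split of n cells across composition fractions
## (largest-remainder apportionment; stable tie order).
largestRemainderCounts <- function(frac, n) {
  raw <- frac * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

## Sequential placement with a minimum-spacing rejection rule. A "skeleton"
## chain of cells along a randomly oriented diameter pins the aggregate's
## Feret extent at ~2*radius and guarantees one connected chain; remaining
## cells are grown within packing spacing of an existing cell, no two cells
## closer than spacing/2.
placeTLSCells <- function(cx, cy, r, n, spacing) {
  minSep <- spacing / 2
  theta <- runif(1L, 0, pi)
  nSkel <- min(n, ceiling(2 * r / spacing) + 1L)
  t <- if (nSkel == 1L) 0 else seq(-r, r, length.out = nSkel)
  px <- cx + t * cos(theta)
  py <- cy + t * sin(theta)
  minSep2 <- minSep^2
  r2 <- r^2
  k <- length(px)
  px <- c(px, numeric(n - k))
  py <- c(py, numeric(n - k))
  B <- 64L
  while (k < n) {
    tries <- 0L
    repeat {
      ## batch of candidate positions, each grown from a random anchor
      a <- sample.int(k, B, replace = TRUE)
      d <- runif(B, minSep, spacing)
      ang <- runif(B, 0, 2 * pi)
      qx <- px[a] + d * cos(ang)
      qy <- py[a] + d * sin(ang)
      cand <- which((qx - cx)^2 + (qy - cy)^2 <= r2)
      hit <- NA_integer_
      cur <- seq_len(k)
      for (b in cand) {
        if (min((px[cur] - qx[b])^2 + (py[cur] - qy[b])^2) >= minSep2) {
          hit <- b
          break
        }
      }
      if (!is.na(hit)) break
      tries <- tries + B
      if (tries > 20000L)
        stopf("cannot place %d cells in a TLS disc of radius %g at spacing %g",
              n, r, spacing)
    }
    k <- k + 1L
    px[k] <- qx[hit]
    py[k] <- qy[hit]
  }
  cbind(x = px, y = py)
}

## rows of zeros for every marker, then set template-positive markers to 1
markersForTemplates <- function(labels) {
  mk <- markerUniverse()
  tmpl <- phenotypeTemplates()
  m <- matrix(0L, length(labels), length(mk), dimnames = list(NULL, mk))
  for (lab in unique(labels)) {
    pos <- tmpl[[lab]]
    if (length(pos)) m[labels == lab, pos] <- 1L
  }
  m
}

#' Simulate one multiplexed slide with known ground truth
#'
#' Generates the union of (i) homogeneous Poisson background processes per
#' phenotype template, (ii) PanCK+ tumor-nest cells uniform in nest discs,
#' and (iii) planted TLS aggregates placed inside their discs so each forms
#' a single connected component at the contact distance. Background and
#' nest cells falling within \code{guardMarginUm} of a TLS disc are
#' removed. With \code{markerFlipRate = 0} every planted marker flag is
#' exact; otherwise each marker of each cell is independently flipped.
#' Generation is a pure function of the config (including its seed).
#'
#' @param config a \linkS4class{SlideConfig}.
#' @return list with elements \code{table} (a \linkS4class{CellTable}) and
#'   \code{truth} (list per TLS spec: \code{tls_id}, \code{status},
#'   \code{member_ids}, \code{n_cells}).
#' @examples
#' sl <- simulateSlide(SlideConfig(backgroundRates = c(CD8T = 50), seed = 7))
#' nCells(sl$table)
#' @export
simulateSlide <- function(config) {
  stopifnot(is(config, "SlideConfig"))
  validObject(config)
  withSeed(config@seed, {
    w <- config@fieldWidthUm
    h <- config@fieldHeightUm
    xs <- list(); ys <- list(); labs <- list()
    origin <- list()
    ## planted TLS aggregates
    truthSizes <- integer(0)
    for (k in seq_along(config@tlsSpecs)) {
      s <- config@tlsSpecs[[k]]
      validObject(s)
      pts <- placeTLSCells(s@center[1L], s@center[2L], s@radiusUm,
                           s@nCells, s@packingSpacingUm)
      comp <- s@composition[s@composition > 0]
      cnt <- largestRemainderCounts(comp, s@nCells)
      names(cnt) <- names(comp)
      ## maturity guarantees: at least one FDC of the required kind
      needed <- switch(s@maturity, mature_primary = "FDC21",
                       mature_secondary = "FDC21_23", NULL)
      if (!is.null(needed) && cnt[[needed]] == 0L) {
        donor <- names(cnt)[which.max(cnt)]
        cnt[[donor]] <- cnt[[donor]] - 1L
        cnt[[needed]] <- 1L
      }
      lab <- sample(rep(names(cnt), cnt))
      xs[[length(xs) + 1L]] <- pts[, 1L]
      ys[[length(ys) + 1L]] <- pts[, 2L]
      labs[[length(labs) + 1L]] <- lab
      origin[[length(origin) + 1L]] <- rep(paste0("tls", k), s@nCells)
      truthSizes[k] <- s@nCells
    }
    ## tumor nests
    nests <- config@tumorNests
    for (k in seq_len(nrow(nests))) {
      areaMm2 <- pi * nests$radius_um[k]^2 * 1e-6
      nN <- rpois(1L, nests$rate[k] * areaMm2)
      if (nN == 0L) next
      rr <- nests$radius_um[k] * sqrt(runif(nN))
      aa <- runif(nN, 0, 2 * pi)
      xs[[length(xs) + 1L]] <- nests$x_um[k] + rr * cos(aa)
      ys[[length(ys) + 1L]] <- nests$y_um[k] + rr * sin(aa)
      labs[[length(labs) + 1L]] <- rep("Tumor", nN)
      origin[[length(origin) + 1L]] <- rep("nest", nN)
    }
    ## Poisson background
    fieldAreaMm2 <- w * h * 1e-6
    for (ph in names(config@backgroundRates)) {
      nB <- rpois(1L, config@backgroundRates[[ph]] * fieldAreaMm2)
      if (nB == 0L) next
      xs[[length(xs) + 1L]] <- runif(nB, 0, w)
      ys[[length(ys) + 1L]] <- runif(nB, 0, h)
      labs[[length(labs) + 1L]] <- rep(ph, nB)
      origin[[length(origin) + 1L]] <- rep("background", nB)
    }
    x <- unlist(xs) %||% numeric(0)
    y <- unlist(ys) %||% numeric(0)
    lab <- unlist(labs) %||% character(0)
    org <- unlist(origin) %||% character(0)
    ## clear a guard ring around every TLS disc
    if (length(config@tlsSpecs) && length(x)) {
      keep <- rep(TRUE, length(x))
      isTls <- startsWith(org, "tls")
      for (s in config@tlsSpecs) {
        lim2 <- (s@radiusUm + config@guardMarginUm)^2
        near <- (x - s@center[1L])^2 + (y - s@center[2L])^2 <= lim2
        keep <- keep & (isTls | !near)
      }
      x <- x[keep]; y <- y[keep]; lab <- lab[keep]; org <- org[keep]
    }
    n <- length(x)
    mk <- markersForTemplates(lab)
    if (config@markerFlipRate > 0 && n > 0L) {
      flips <- matrix(runif(n * ncol(mk)) < config@markerFlipRate,
                      n, ncol(mk))
      mk[flips] <- 1L - mk[flips]
    }
    ids <- if (n) sprintf("c%05d", seq_len(n)) else character(0)
    df <- data.frame(cell_id = ids, x_um = round(x, 3L), y_um = round(y, 3L),
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(mk, check.names = FALSE))
    tab <- CellTable(df, sampleId = paste0("slide_seed", config@seed),
                     markerNames = markerUniverse())
    truth <- lapply(seq_along(config@tlsSpecs), function(k) {
      s <- config@tlsSpecs[[k]]
      list(tls_id = paste0("tls", k),
           status = switch(s@maturity, early = "eTLS",
                           mature_primary = "mTLS_primary",
                           mature_secondary = "mTLS_secondary"),
           member_ids = ids[org == paste0("tls", k)],
           n_cells = s@nCells)
    })
    list(table = tab, truth = truth)
  })
}
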