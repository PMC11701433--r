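#' @importFrom stats median pnorm pchisq qnorm rbinom rnorm rexp rpois runif
#' @importFrom utils read.csv write.csv combn head
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Fixed decimal formatting for deterministic text output (micron coordinates
## are kept at nm precision throughout the package).
fmtUm <- function(x) sprintf("%.3f", x)

isBinary01 <- function(v) all(v %in% c(0, 1))

## Shoelace area of an open ring (first vertex not repeated), in input units^2.
polygonArea <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Ray-casting point-in-polygon with an explicit on-boundary test; points on
## an edge or vertex count as inside (closed-polygon convention).
pointsInPolygon <- function(px, py, coords, eps = 1e-9) {
  vx <- coords[, 1]; vy <- coords[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    seglen <- max(sqrt((xj - xi)^2 + (yj - yi)^2), eps)
    within <- px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onedge <- onedge | (abs(cross) <= eps * seglen & within)
    denom <- yj - yi
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / denom
      crosses <- crosses & (px < xint)
    }
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

## TRUE if any two non-adjacent edges of the open ring properly intersect.
ringSelfIntersects <- function(coords) {
  n <- nrow(coords)
  if (n < 4L) return(FALSE)
  seg <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      ## skip adjacent segments (share a vertex)
      if (b == a + 1L || (a == 1L && b == n)) next
      p1 <- coords[seg[a, 1L], ]; p2 <- coords[seg[a, 2L], ]
      p3 <- coords[seg[b, 1L], ]; p4 <- coords[seg[b, 2L], ]
      d1 <- orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
      d2 <- orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
      d3 <- orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
      d4 <- orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
      if (d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

## Maximum pairwise distance of a point set (Feret diameter). Uses the convex
## hull when available so large aggregates stay cheap.
feretDiameter <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  if (n > 3L) {
    h <- grDevices::chull(x, y)
    if (length(h) >= 3L) { x <- x[h]; y <- y[h] }
  }
  max(stats::dist(cbind(x, y)))
}

## All unordered pairs (i, j), i < j, with Euclidean distance <= r, found by
## bucketing points on a grid of cell size r (fixed-radius neighbor search).
neighborPairs <- function(x, y, r) {
  if (!is.finite(r) || r <= 0) stopf("contact distance must be positive")
  n <- length(x)
  empty <- cbind(i = integer(0), j = integer(0))
  if (n < 2L) return(empty)
  gx <- as.integer(floor(x / r))
  gy <- as.integer(floor(y / r))
  keys <- paste(gx, gy, sep = ",")
  buckets <- split(seq_len(n), keys)
  bx <- as.integer(sub(",.*$", "", names(buckets)))
  by <- as.integer(sub("^.*,", "", names(buckets)))
  ## half-plane of neighbor offsets: every unordered bucket pair visited once
  off <- cbind(c(0L, 1L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L, -1L))
  acc <- vector("list", 0L)
  k <- 0L
  r2 <- r * r
  for (b in seq_along(buckets)) {
    ia <- buckets[[b]]
    for (o in seq_len(nrow(off))) {
      if (o == 1L) {
        ib <- ia
        if (length(ia) < 2L) next
      } else {
        nb <- paste(bx[b] + off[o, 1L], by[b] + off[o, 2L], sep = ",")
        ib <- buckets[[nb]]
        if (is.null(ib)) next
      }
      dx <- outer(x[ia], x[ib], "-")
      dy <- outer(y[ia], y[ib], "-")
      hit <- which(dx * dx + dy * dy <= r2, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      pi <- ia[hit[, 1L]]
      pj <- ib[hit[, 2L]]
      keep <- if (o == 1L) pi < pj else rep(TRUE, length(pi))
      if (!any(keep)) next
      k <- k + 1L
      acc[[k]] <- cbind(pmin(pi[keep], pj[keep]), pmax(pi[keep], pj[keep]))
    }
  }
  if (k == 0L) return(empty)
  m <- do.call(rbind, acc)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  colnames(m) <- c("i", "j")
  m
}
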