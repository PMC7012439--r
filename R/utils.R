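## Internal geometry and numeric helpers.

#' @importFrom stats setNames approx rnorm runif median
#' @importFrom utils read.csv write.csv head tail
NULL

.asCoordMatrix <- function(x) {
  if (is(x, "PointSet")) return(x@points)
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) != 2L) {
    if (length(m) == 2L) m <- matrix(as.numeric(m), 1L, 2L)
    else stop("expected a two-column coordinate matrix")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

## squared Euclidean cross-distances: |a_i - b_j|^2, (nrow(A) x nrow(B))
.crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## vertex closure of a polygon's edge list (closed: wrap to first vertex)
.edgeEnds <- function(Q, closed) {
  n <- nrow(Q)
  if (closed) list(a = Q, b = Q[c(2:n, 1L), , drop = FALSE])
  else list(a = Q[-n, , drop = FALSE], b = Q[-1L, , drop = FALSE])
}

## min distance from each point of P to the polyline/polygon Q
.distToPolyline <- function(P, Q, closed = TRUE) {
  P <- .asCoordMatrix(P); Q <- .asCoordMatrix(Q)
  e <- .edgeEnds(Q, closed)
  best <- rep(Inf, nrow(P))
  for (k in seq_len(nrow(e$a))) {
    a <- e$a[k, ]; b <- e$b[k, ]
    ab <- b - a
    L2 <- sum(ab^2)
    pax <- P[, 1L] - a[1L]; pay <- P[, 2L] - a[2L]
    t <- if (L2 > 0) pmin(1, pmax(0, (pax * ab[1L] + pay * ab[2L]) / L2)) else 0
    dx <- pax - t * ab[1L]; dy <- pay - t * ab[2L]
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

## even-odd point-in-polygon; points on the boundary count as inside
.insidePolygon <- function(P, Q, boundaryTol = 1e-9) {
  P <- .asCoordMatrix(P); Q <- .asCoordMatrix(Q)
  n <- nrow(Q)
  x <- P[, 1L]; y <- P[, 2L]
  inside <- rep(FALSE, nrow(P))
  j <- n
  for (i in seq_len(n)) {
    xi <- Q[i, 1L]; yi <- Q[i, 2L]
    xj <- Q[j, 1L]; yj <- Q[j, 2L]
    crosses <- ((yi > y) != (yj > y))
    if (any(crosses)) {
      xin <- (xj - xi) * (y - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & (x < xin))
    }
    j <- i
  }
  inside | (.distToPolyline(P, Q, closed = TRUE) <= boundaryTol)
}

## cumulative arc length of a polyline given as a vertex matrix
.arcLengths <- function(Q) {
  d <- sqrt(rowSums((Q[-1L, , drop = FALSE] - Q[-nrow(Q), , drop = FALSE])^2))
  c(0, cumsum(d))
}

## signed polygon area (positive = counter-clockwise)
.signedArea <- function(Q) {
  n <- nrow(Q)
  xs <- Q[, 1L]; ys <- Q[, 2L]
  sum(xs * ys[c(2:n, 1L)] - xs[c(2:n, 1L)] * ys) / 2
}

## run code with a locally seeded RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## structured one-line logger used by batch runs
.logLine <- function(level, fmt, ..., con = stderr(), minLevel = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] < levels[[minLevel]]) return(invisible(NULL))
  cat(sprintf("[%s] %s\n", level, sprintf(fmt, ...)), file = con)
  invisible(NULL)
}
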