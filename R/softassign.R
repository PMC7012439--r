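#' Softassign correspondence update
#'
#' Builds the fuzzy correspondence matrix between the warped source points
#' \eqn{f(v_j)} and the target points \eqn{x_i} at temperature \code{T}.
#' Inner entries are initialised as Gaussian affinities
#' \eqn{m_{ij} \propto \exp(-\|x_i - f(v_j)\|^2 / 2T) / T}; the outlier bins
#' (row 1 and column 1 of the returned matrix) use a fixed temperature
#' \code{outlierT} and are centred at the opposing set's centroid, so both
#' point sets can shed points with no counterpart. The matrix is then driven
#' towards doubly stochastic form by alternating row/column (Sinkhorn)
#' normalisation of the non-outlier rows and columns.
#'
#' @param warpedSource K x 2 matrix of warped source coordinates
#'   \eqn{f(v_j)}.
#' @param target N x 2 matrix (or [PointSet-class]) of target points.
#' @param T temperature (squared distance units of the working frame); > 0.
#' @param outlierT outlier-bin temperature, held at the initial annealing
#'   temperature by [annealRegister()].
#' @param tol maximum tolerated deviation of inner row/column sums from 1.
#' @param maxSweeps maximum normalisation sweeps.
#' @return An (N+1) x (K+1) non-negative matrix; \code{m[1, ]} and
#'   \code{m[, 1]} are the outlier bins, \code{m[i + 1, j + 1]} the
#'   correspondence of target point i to source point j.
#' @examples
#' src <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' m <- softassignUpdate(src, src, T = 1e-4, outlierT = 0.5)
#' round(m[-1, -1], 3)   # ~ identity: points match themselves
#' @export
softassignUpdate <- function(warpedSource, target, T, outlierT,
                             tol = 1e-3, maxSweeps = 30L) {
  FV <- .asCoordMatrix(warpedSource)
  X <- .asCoordMatrix(target)
  if (!all(is.finite(FV)) || !all(is.finite(X)))
    stop("softassignUpdate: non-finite coordinates")
  if (T <= 0 || outlierT <= 0)
    stop("temperatures must be positive")
  N <- nrow(X); K <- nrow(FV)

  m <- matrix(0, N + 1L, K + 1L)
  m[-1L, -1L] <- exp(-.crossDist2(X, FV) / (2 * T)) / T
  cenSrc <- colMeans(FV)
  cenTgt <- colMeans(X)
  dX <- sweep(X, 2L, cenSrc)          # target points vs warped-source centroid
  m[-1L, 1L] <- exp(-rowSums(dX^2) / (2 * outlierT)) / outlierT
  dV <- sweep(FV, 2L, cenTgt)         # warped source points vs target centroid
  m[1L, -1L] <- exp(-rowSums(dV^2) / (2 * outlierT)) / outlierT

  # guard against full underflow of a row/column (points extremely far out)
  eps <- .Machine$double.xmin
  for (sweepIt in seq_len(maxSweeps)) {
    rs <- rowSums(m[-1L, , drop = FALSE])
    m[-1L, ] <- m[-1L, , drop = FALSE] / pmax(rs, eps)
    cs <- colSums(m[, -1L, drop = FALSE])
    m[, -1L] <- sweep(m[, -1L, drop = FALSE], 2L, pmax(cs, eps), "/")
    dev <- max(abs(rowSums(m[-1L, , drop = FALSE]) - 1))
    if (dev < tol) break
  }
  m
}

#' Register two preprocessed point sets with modified TPS-RPM
#'
#' Core matching loop of the modified thin-plate-spline robust point matching
#' algorithm: alternate [softassignUpdate()] correspondence estimation and
#' regularised [tpsSolve()] transform estimation while a deterministic
#' annealing schedule lowers the temperature. The TPS penalty is annealed
#' with the temperature (\eqn{\lambda = \lambda_0 T K}) so the transform is
#' near-rigid while correspondence is still fuzzy and becomes increasingly
#' non-rigid as matches harden, which lets the matcher escape local optima
#' under large deformations. Outlier bins on both sides make the matching
#' robust to points without a counterpart in either set.
#'
#' Both inputs are expected in a shared unit box (see [toUnitBox()] with a
#' common [unitBoxScaling()]); [registerPair()] wraps the full mm-space
#' pipeline. The loop is fully deterministic.
#'
#' @param source,target [PointSet-class] objects (or coordinate matrices) in
#'   shared unit-box coordinates.
#' @param schedule an [AnnealingSchedule-class].
#' @param tInit,tFinal optional explicit initial/final temperatures
#'   (unit-box squared distances). By default \code{tInit} is
#'   \code{tInitFactor} times the mean squared source-target distance and
#'   \code{tFinal} is \code{tFinalFactor} times the squared median
#'   nearest-neighbour spacing of the target.
#' @return A list with elements \code{transform} (the final
#'   [TpsTransform-class] in unit-box coordinates), \code{correspondence}
#'   (the final softassign matrix, see [softassignUpdate()]) and
#'   \code{diagnostics} (a data.frame with one row per outer iteration:
#'   temperature, lambda, weighted RMS residual, outlier mass and bending
#'   energy).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 41)[-41]
#' src <- pointSet(cbind(0.5 + 0.3 * cos(th), 0.5 + 0.2 * sin(th)))
#' res <- annealRegister(src, src, annealingSchedule())
#' max(abs(transformPoints(res$transform, coords(src)) - coords(src)))
#' @export
annealRegister <- function(source, target, schedule = annealingSchedule(),
                           tInit = NULL, tFinal = NULL) {
  V <- .asCoordMatrix(source)
  X <- .asCoordMatrix(target)
  K <- nrow(V)
  stopifnot(is(schedule, "AnnealingSchedule"))

  if (is.null(tInit))
    tInit <- schedule@tInitFactor * mean(.crossDist2(X, V))
  if (is.null(tFinal)) {
    nn2 <- .crossDist2(X, X)
    diag(nn2) <- Inf
    tFinal <- schedule@tFinalFactor * median(apply(nn2, 1L, min))
  }
  if (tInit <= tFinal)
    tInit <- tFinal * 2  # degenerate geometry; still run at least one level

  f <- .identityTransform(V)
  m <- NULL
  trace <- list()
  Tcur <- tInit
  iter <- 0L
  while (Tcur >= tFinal) {
    iter <- iter + 1L
    lam <- schedule@lambdaInit * Tcur * K
    lam2 <- schedule@lambda2Init * Tcur * K
    for (inner in seq_len(schedule@innerIters)) {
      fV <- transformPoints(f, V)
      m <- softassignUpdate(fV, X, T = Tcur, outlierT = tInit,
                            tol = schedule@sinkhornTol,
                            maxSweeps = schedule@sinkhornMaxSweeps)
      inner_m <- m[-1L, -1L, drop = FALSE]
      w <- colSums(inner_m)
      Y <- crossprod(inner_m, X) / pmax(w, .Machine$double.xmin)
      f <- tryCatch(tpsSolve(V, Y, weights = w, lam = lam, lam2 = lam2),
                    error = function(e)
                      stop(sprintf("TPS solve failed at outer iteration %d (T = %.3g): %s",
                                   iter, Tcur, conditionMessage(e)),
                           call. = FALSE))
    }
    fV <- transformPoints(f, V)
    wsum <- sum(w)
    rowsOut <- sum(max.col(m[-1L, , drop = FALSE]) == 1L)
    colsOut <- sum(apply(m[, -1L, drop = FALSE], 2L, which.max) == 1L)
    trace[[iter]] <- data.frame(
      iter = iter, T = Tcur, lambda = lam,
      residual = sqrt(sum(w * rowSums((fV - Y)^2)) / max(wsum, 1e-12)),
      outlierMass = (nrow(X) + K - 2 * sum(inner_m)) / (nrow(X) + K),
      nOutlierAssigned = rowsOut + colsOut,
      bending = bendingEnergy(f))
    Tcur <- Tcur * schedule@rate
  }
  list(transform = f, correspondence = m,
       diagnostics = do.call(rbind, trace))
}
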