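## Thin-plate-spline kernel U(r) = r^2 log r, written in terms of r^2 to
## avoid the sqrt: U = 0.5 * r2 * log(r2), with U(0) = 0.
.tpsKernel <- function(r2) {
  u <- matrix(0, nrow(r2), ncol(r2))
  pos <- r2 > 0
  u[pos] <- 0.5 * r2[pos] * log(r2[pos])
  u
}

.identityTransform <- function(V) {
  new("TpsTransform", controlPoints = V, linear = diag(2),
      translation = c(0, 0),
      warpCoeffs = matrix(0, nrow(V), 2L))
}

#' Solve a weighted, regularised thin-plate-spline fit
#'
#' Finds the TPS transform minimising
#' \deqn{\sum_j w_j \| f(v_j) - y_j \|^2 + \lambda\, E_{bend}(f)
#'       + \lambda_2 \| L - I \|_F^2,}
#' where \eqn{E_{bend}} is the TPS bending energy and \eqn{L} the linear
#' part of the affine component. The warp coefficients are parameterised in
#' the null space of the side conditions (\eqn{\sum w = 0}, \eqn{\sum w v =
#' 0}) via a QR decomposition of \eqn{[1\; V]}, so the conditions hold
#' exactly and warp and affine parts are solved jointly in one dense linear
#' solve.
#'
#' At \code{lam = 0}, \code{lam2 = 0} with positive weights and distinct
#' points the solution interpolates (\eqn{f(v_j) = y_j}). As \code{lam}
#' grows the warp vanishes and the fit tends to the weighted least-squares
#' affine map. \code{lam2} breaks ties among data-equivalent affine maps
#' towards the identity; within the annealing loop it keeps the transform
#' from sliding tangentially along near-symmetric contours (translation is
#' never penalised).
#'
#' Points with weight below \code{dropTol} carry no information (within
#' TPS-RPM they are pure outliers) and are dropped from the solve; the
#' returned transform keeps only the retained control points but is defined
#' on the whole plane.
#'
#' @param source K x 2 matrix (or [PointSet-class]) of pairwise-distinct
#'   control points \eqn{v_j}.
#' @param virtualTargets K x 2 matrix of target coordinates \eqn{y_j}.
#' @param weights non-negative per-point weights, not all zero. Default all 1.
#' @param lam bending-energy weight \eqn{\lambda \ge 0}.
#' @param lam2 affine-identity ridge \eqn{\lambda_2 \ge 0}; default 0.
#' @param dropTol weight threshold below which a point is excluded.
#' @return A [TpsTransform-class].
#' @examples
#' v <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
#' f <- tpsSolve(v, v + rep(c(2, 3), each = 5))
#' max(abs(transformPoints(f, v) - (v + rep(c(2, 3), each = 5))))
#' @export
tpsSolve <- function(source, virtualTargets, weights = NULL, lam = 0,
                     lam2 = 0, dropTol = 1e-8) {
  V <- .asCoordMatrix(source)
  Y <- .asCoordMatrix(virtualTargets)
  K <- nrow(V)
  if (nrow(Y) != K)
    stop("virtualTargets must have one row per source point")
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K || any(weights < 0) || !any(weights > 0))
    stop("weights must be non-negative, one per point, not all zero")
  if (lam < 0 || lam2 < 0) stop("lam and lam2 must be >= 0")

  keep <- weights > dropTol
  if (sum(keep) < 3L)
    stop("fewer than 3 source points carry weight; cannot solve TPS")
  V <- V[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  w <- weights[keep]
  K <- nrow(V)

  Phi <- .tpsKernel(.crossDist2(V, V))
  P <- cbind(1, V)
  nW <- K - 3L
  Qfull <- qr.Q(qr(P), complete = TRUE)
  Q2 <- Qfull[, -(1:3), drop = FALSE]       # null space of t(P)
  B <- Phi %*% Q2                           # warp basis evaluated at V

  # normal equations for (gamma, A); W = Q2 gamma
  DB <- B * w
  DP <- P * w
  S <- diag(c(0, 1, 1))                     # penalise linear part only
  A0 <- rbind(0, diag(2))                   # identity affine (translation 0)
  M <- rbind(
    cbind(crossprod(B, DB) + lam * crossprod(Q2, B), crossprod(B, DP)),
    cbind(crossprod(P, DB), crossprod(P, DP) + lam2 * S))
  rhs <- rbind(crossprod(DB, Y), crossprod(DP, Y) + lam2 * (S %*% A0))
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("singular TPS system (degenerate or collinear control points); ",
         "use lam > 0 or check the input contour", call. = FALSE))

  W <- if (nW > 0L) Q2 %*% sol[seq_len(nW), , drop = FALSE]
       else matrix(0, K, 2L)
  aff <- sol[nW + 1:3, , drop = FALSE]
  new("TpsTransform", controlPoints = V, linear = aff[2:3, , drop = FALSE],
      translation = as.numeric(aff[1L, ]), warpCoeffs = W)
}

#' @rdname transformPoints
#' @export
setMethod("transformPoints", signature("TpsTransform", "matrix"),
          function(transform, points) {
  U <- .tpsKernel(.crossDist2(points, transform@controlPoints))
  points %*% transform@linear +
    matrix(transform@translation, nrow(points), 2L, byrow = TRUE) +
    U %*% transform@warpCoeffs
})

#' @rdname transformPoints
#' @export
setMethod("transformPoints", signature("TpsTransform", "PointSet"),
          function(transform, points) {
  pointSet(transformPoints(transform, points@points),
           closed = points@closed)
})

#' Bending energy of a TPS transform
#'
#' The thin-plate bending energy \eqn{\mathrm{tr}(W^\top \Phi W)} of the
#' non-affine part, where \eqn{\Phi} is the kernel matrix among control
#' points. Zero for purely affine transforms; grows as the warp becomes less
#' rigid.
#'
#' @param transform a [TpsTransform-class].
#' @return Non-negative scalar.
#' @export
bendingEnergy <- function(transform) {
  stopifnot(is(transform, "TpsTransform"))
  W <- transform@warpCoeffs
  if (nrow(W) == 0L) return(0)
  Phi <- .tpsKernel(.crossDist2(transform@controlPoints,
                                transform@controlPoints))
  max(0, sum(W * (Phi %*% W)))
}

#' Conjugate a unit-box TPS transform back to mm coordinates
#'
#' Given a transform \eqn{f_u} estimated in unit-box coordinates and the
#' [UnitBoxScaling-class] \code{u = (x - o) / s}, returns the mm-space
#' transform \eqn{f(x) = s\,f_u((x - o)/s) + o} as an explicit
#' [TpsTransform-class]. The TPS family is closed under this similarity
#' conjugation because the side conditions absorb the kernel's
#' \eqn{\log}-scale cross terms into the translation.
#'
#' @param transform a [TpsTransform-class] in unit-box coordinates.
#' @param scaling the shared [UnitBoxScaling-class] of the registered pair.
#' @return A [TpsTransform-class] acting on mm coordinates.
#' @export
rescaleTransform <- function(transform, scaling) {
  stopifnot(is(transform, "TpsTransform"), is(scaling, "UnitBoxScaling"))
  s <- scaling@scale
  o <- scaling@offset
  Vmm <- sweep(transform@controlPoints * s, 2L, o, "+")
  Wmm <- transform@warpCoeffs / s
  # constant from U(r/s) = (r^2 log r - r^2 log s)/s^2 under the side
  # conditions: only sum_j w_j |v_j^mm|^2 survives
  c0 <- as.numeric(crossprod(rowSums(Vmm^2), transform@warpCoeffs)) / s
  tmm <- s * transform@translation + o -
    as.numeric(o %*% transform@linear) - log(s) * c0
  new("TpsTransform", controlPoints = Vmm, linear = transform@linear,
      translation = tmm, warpCoeffs = Wmm)
}
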