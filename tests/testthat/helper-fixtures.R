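## Shared geometric fixtures and independent oracles, built in code.

# axis-aligned rectangle contour (corners only)
rectContour <- function(w = 10, h = 10, at = c(0, 0)) {
  pointSet(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)) +
             matrix(at, 4L, 2L, byrow = TRUE))
}

# dense circle polygon
circleContour <- function(radius = 10, n = 720, at = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pointSet(cbind(at[1L] + radius * cos(th), at[2L] + radius * sin(th)))
}

# asymmetric smooth blob (no rotational symmetry, so correspondence is
# well defined)
blobContour <- function(radius = 12, n = 76, at = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- radius * (1 + 0.12 * cos(2 * th + 0.7) + 0.08 * cos(3 * th + 2.1) +
                   0.05 * cos(4 * th + 4.0))
  pointSet(cbind(at[1L] + r * cos(th), at[2L] + r * sin(th)))
}

rotationMatrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
}

# Independent TPS evaluator: plain per-point loop over the analytic formula,
# sharing no code with the package's vectorised evaluation.
oracleTpsEval <- function(tf, pts) {
  V <- tf@controlPoints
  out <- matrix(NA_real_, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    acc <- as.numeric(p %*% tf@linear) + tf@translation
    for (j in seq_len(nrow(V))) {
      r <- sqrt(sum((p - V[j, ])^2))
      if (r > 0) acc <- acc + tf@warpCoeffs[j, ] * r^2 * log(r)
    }
    out[i, ] <- acc
  }
  out
}

# Independent interpolating-TPS solve: classic bordered linear system
# [Phi P; P' 0], assembled with plain loops.
oracleTpsInterpolate <- function(V, Y) {
  K <- nrow(V)
  Phi <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    r <- sqrt(sum((V[i, ] - V[j, ])^2))
    if (r > 0) Phi[i, j] <- r^2 * log(r)
  }
  P <- cbind(1, V)
  M <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, 3L, 3L)))
  sol <- solve(M, rbind(Y, matrix(0, 3L, 2L)))
  list(W = sol[1:K, , drop = FALSE], aff = sol[K + 1:3, , drop = FALSE],
       V = V)
}

oracleTpsInterpEval <- function(fit, pts) {
  out <- matrix(NA_real_, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    acc <- fit$aff[1L, ] + p[1L] * fit$aff[2L, ] + p[2L] * fit$aff[3L, ]
    for (j in seq_len(nrow(fit$V))) {
      r <- sqrt(sum((p - fit$V[j, ])^2))
      if (r > 0) acc <- acc + fit$W[j, ] * r^2 * log(r)
    }
    out[i, ] <- acc
  }
  out
}

# brute-force min distance from points to a dense sampling of a polygon,
# used as an independent oracle for contour distances
oracleDistToPolygon <- function(pts, poly, step = 1e-3) {
  n <- nrow(poly)
  dense <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    t <- seq(0, 1, by = step / max(step, sqrt(sum((b - a)^2))))
    cbind(a[1L] + t * (b[1L] - a[1L]), a[2L] + t * (b[2L] - a[2L]))
  }))
  vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((dense[, 1L] - pts[i, 1L])^2 + (dense[, 2L] - pts[i, 2L])^2)),
    numeric(1))
}

# build a pure-translation TpsTransform from a small control square
translationTransform <- function(t, at = c(0, 0)) {
  v <- coords(rectContour(4, 4, at))
  tpsSolve(v, v + matrix(t, 4L, 2L, byrow = TRUE))
}

# a smooth synthetic TPS warp for composition/recovery tests
smoothWarpTransform <- function(seed, sd = 0.8, box = c(0, 20)) {
  set.seed(seed)
  ctrl <- as.matrix(expand.grid(seq(box[1L], box[2L], length.out = 3L),
                                seq(box[1L], box[2L], length.out = 3L)))
  dimnames(ctrl) <- NULL
  tpsSolve(ctrl, ctrl + matrix(rnorm(length(ctrl), sd = sd), ncol = 2L),
           lam = 1)
}
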