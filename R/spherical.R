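#' Real spherical harmonics up to l = 3
#'
#' Orthonormal real spherical harmonics Y_lm evaluated on the direction of a
#' displacement vector, in the standard Cartesian polynomial form without the
#' Condon-Shortley phase.  Components are ordered (l, m) = (0,0), (1,-1),
#' (1,0), (1,1), (2,-2) ... (3,3); index of (l, m) is l^2 + l + m + 1.
#'
#' @param disp n x 3 matrix of displacement vectors (need not be normalized).
#' @param l_max maximum angular order (0..3).
#' @return matrix n x (l_max+1)^2 of Y values.
#' @keywords internal
sph_harmonics <- function(disp, l_max = 3L) {
  stopifnot(l_max >= 0L, l_max <= 3L)
  x <- disp[, 1]; y <- disp[, 2]; z <- disp[, 3]
  r2 <- x^2 + y^2 + z^2
  r <- sqrt(r2)
  ne <- length(x)
  nlm <- (l_max + 1L)^2
  Y <- matrix(0.0, ne, nlm)
  Y[, 1] <- 0.28209479177387814
  if (l_max >= 1L) {
    c1 <- 0.4886025119029199
    Y[, 2] <- c1 * y / r
    Y[, 3] <- c1 * z / r
    Y[, 4] <- c1 * x / r
  }
  if (l_max >= 2L) {
    c22 <- 1.0925484305920792; c20 <- 0.31539156525252005
    c2p2 <- 0.5462742152960396
    Y[, 5] <- c22 * x * y / r2
    Y[, 6] <- c22 * y * z / r2
    Y[, 7] <- c20 * (2 * z^2 - x^2 - y^2) / r2
    Y[, 8] <- c22 * x * z / r2
    Y[, 9] <- c2p2 * (x^2 - y^2) / r2
  }
  if (l_max >= 3L) {
    r3 <- r2 * r
    c33 <- 0.5900435899266435; c32 <- 2.890611442640554
    c31 <- 0.4570457994644658; c30 <- 0.3731763325901154
    c3p2 <- 1.445305721320277
    Y[, 10] <- c33 * y * (3 * x^2 - y^2) / r3
    Y[, 11] <- c32 * x * y * z / r3
    Y[, 12] <- c31 * y * (4 * z^2 - x^2 - y^2) / r3
    Y[, 13] <- c30 * z * (2 * z^2 - 3 * x^2 - 3 * y^2) / r3
    Y[, 14] <- c31 * x * (4 * z^2 - x^2 - y^2) / r3
    Y[, 15] <- c3p2 * z * (x^2 - y^2) / r3
    Y[, 16] <- c33 * x * (x^2 - 3 * y^2) / r3
  }
  Y
}

#' Gradients of the real spherical harmonics
#'
#' Returns the Cartesian gradient of each Y_lm with respect to the
#' displacement vector: Y_lm = P_lm(x,y,z) / r^l with P_lm homogeneous of
#' degree l, so grad Y = (grad P) / r^l - l P u / r^(l+2).
#'
#' @param disp n x 3 matrix of displacement vectors.
#' @param l_max maximum angular order (0..3).
#' @return list of three n x (l_max+1)^2 matrices `gx`, `gy`, `gz`.
#' @keywords internal
sph_harmonics_grad <- function(disp, l_max = 3L) {
  stopifnot(l_max >= 0L, l_max <= 3L)
  x <- disp[, 1]; y <- disp[, 2]; z <- disp[, 3]
  r2 <- x^2 + y^2 + z^2
  ne <- length(x)
  nlm <- (l_max + 1L)^2
  ## homogeneous polynomials P and their gradients
  P <- matrix(0.0, ne, nlm)
  PX <- matrix(0.0, ne, nlm); PY <- matrix(0.0, ne, nlm); PZ <- matrix(0.0, ne, nlm)
  P[, 1] <- 0.28209479177387814
  lofi <- rep(0L, nlm)
  if (l_max >= 1L) {
    c1 <- 0.4886025119029199
    lofi[2:4] <- 1L
    P[, 2] <- c1 * y; PY[, 2] <- c1
    P[, 3] <- c1 * z; PZ[, 3] <- c1
    P[, 4] <- c1 * x; PX[, 4] <- c1
  }
  if (l_max >= 2L) {
    c22 <- 1.0925484305920792; c20 <- 0.31539156525252005
    c2p2 <- 0.5462742152960396
    lofi[5:9] <- 2L
    P[, 5] <- c22 * x * y; PX[, 5] <- c22 * y; PY[, 5] <- c22 * x
    P[, 6] <- c22 * y * z; PY[, 6] <- c22 * z; PZ[, 6] <- c22 * y
    P[, 7] <- c20 * (2 * z^2 - x^2 - y^2)
    PX[, 7] <- -2 * c20 * x; PY[, 7] <- -2 * c20 * y; PZ[, 7] <- 4 * c20 * z
    P[, 8] <- c22 * x * z; PX[, 8] <- c22 * z; PZ[, 8] <- c22 * x
    P[, 9] <- c2p2 * (x^2 - y^2); PX[, 9] <- 2 * c2p2 * x; PY[, 9] <- -2 * c2p2 * y
  }
  if (l_max >= 3L) {
    c33 <- 0.5900435899266435; c32 <- 2.890611442640554
    c31 <- 0.4570457994644658; c30 <- 0.3731763325901154
    c3p2 <- 1.445305721320277
    lofi[10:16] <- 3L
    P[, 10] <- c33 * y * (3 * x^2 - y^2)
    PX[, 10] <- 6 * c33 * x * y; PY[, 10] <- 3 * c33 * (x^2 - y^2)
    P[, 11] <- c32 * x * y * z
    PX[, 11] <- c32 * y * z; PY[, 11] <- c32 * x * z; PZ[, 11] <- c32 * x * y
    P[, 12] <- c31 * y * (4 * z^2 - x^2 - y^2)
    PX[, 12] <- -2 * c31 * x * y
    PY[, 12] <- c31 * (4 * z^2 - x^2 - 3 * y^2)
    PZ[, 12] <- 8 * c31 * y * z
    P[, 13] <- c30 * z * (2 * z^2 - 3 * x^2 - 3 * y^2)
    PX[, 13] <- -6 * c30 * x * z; PY[, 13] <- -6 * c30 * y * z
    PZ[, 13] <- c30 * (6 * z^2 - 3 * x^2 - 3 * y^2)
    P[, 14] <- c31 * x * (4 * z^2 - x^2 - y^2)
    PX[, 14] <- c31 * (4 * z^2 - 3 * x^2 - y^2)
    PY[, 14] <- -2 * c31 * x * y
    PZ[, 14] <- 8 * c31 * x * z
    P[, 15] <- c3p2 * z * (x^2 - y^2)
    PX[, 15] <- 2 * c3p2 * x * z; PY[, 15] <- -2 * c3p2 * y * z
    PZ[, 15] <- c3p2 * (x^2 - y^2)
    P[, 16] <- c33 * x * (x^2 - 3 * y^2)
    PX[, 16] <- 3 * c33 * (x^2 - y^2); PY[, 16] <- -6 * c33 * x * y
  }
  ## Y = P / r^l  =>  grad Y = gradP / r^l - l * P * u / r^(l+2)
  rl <- outer(r2, lofi, function(a, b) a^(b / 2))   # r^l per (edge, lm)
  rl2 <- rl * r2                                     # r^(l+2)
  lmat <- matrix(lofi, ne, nlm, byrow = TRUE)
  gx <- PX / rl - lmat * P * x / rl2
  gy <- PY / rl - lmat * P * y / rl2
  gz <- PZ / rl - lmat * P * z / rl2
  list(gx = gx, gy = gy, gz = gz)
}

## map lm index -> l (0-based orders), for weighting radial channels by l
sph_l_of_index <- function(l_max) {
  unlist(lapply(0:l_max, function(l) rep(l, 2L * l + 1L)))
}
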