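# Closed-form eigenvalues of many symmetric 3x3 matrices at once.
# Inputs are vectors of the six unique entries; returns the three eigenvalue
# vectors sorted ascending by value (l1 <= l2 <= l3). Uses the trigonometric
# solution of the characteristic cubic (numerically safe for the smooth
# Hessian / covariance fields seen here).
eig3_sym <- function(a11, a22, a33, a12, a13, a23) {
  n <- length(a11)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  ok <- p > 1e-300
  if (any(ok)) {
    pi_ <- p[ok]
    b11 <- (a11[ok] - q[ok]) / pi_
    b22 <- (a22[ok] - q[ok]) / pi_
    b33 <- (a33[ok] - q[ok]) / pi_
    b12 <- a12[ok] / pi_
    b13 <- a13[ok] / pi_
    b23 <- a23[ok] / pi_
    detb <- b11 * b22 * b33 + 2 * b12 * b13 * b23 -
      b11 * b23^2 - b22 * b13^2 - b33 * b12^2
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e3 <- q[ok] + 2 * pi_ * cos(phi)
    e1 <- q[ok] + 2 * pi_ * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[ok] - e1 - e3
    l1[ok] <- e1; l2[ok] <- e2; l3[ok] <- e3
  }
  list(l1 = l1, l2 = l2, l3 = l3)
}

# Unit eigenvector belonging to eigenvalue `lam` when the other two
# eigenvalues are `mu1`, `mu2`: columns of (A - mu1 I)(A - mu2 I) span the
# lam-eigenspace. Picks the largest column per matrix; returns an n x 3
# matrix (rows of zero norm are left as c(0, 0, 1) fallback).
eigvec3_sym <- function(a11, a22, a33, a12, a13, a23, mu1, mu2) {
  s <- mu1 + mu2
  pr <- mu1 * mu2
  # A^2 entries
  c11 <- a11^2 + a12^2 + a13^2
  c22 <- a12^2 + a22^2 + a23^2
  c33 <- a13^2 + a23^2 + a33^2
  c12 <- a11 * a12 + a12 * a22 + a13 * a23
  c13 <- a11 * a13 + a12 * a23 + a13 * a33
  c23 <- a12 * a13 + a22 * a23 + a23 * a33
  m11 <- c11 - s * a11 + pr
  m22 <- c22 - s * a22 + pr
  m33 <- c33 - s * a33 + pr
  m12 <- c12 - s * a12
  m13 <- c13 - s * a13
  m23 <- c23 - s * a23
  n1 <- m11^2 + m12^2 + m13^2
  n2 <- m12^2 + m22^2 + m23^2
  n3 <- m13^2 + m23^2 + m33^2
  vx <- m13; vy <- m23; vz <- m33; nn <- n3
  use2 <- n2 > nn
  vx[use2] <- m12[use2]; vy[use2] <- m22[use2]; vz[use2] <- m23[use2]
  nn[use2] <- n2[use2]
  use1 <- n1 > nn
  vx[use1] <- m11[use1]; vy[use1] <- m12[use1]; vz[use1] <- m13[use1]
  nn[use1] <- n1[use1]
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  bad <- !is.finite(nrm) | nrm < 1e-12
  vx[bad] <- 0; vy[bad] <- 0; vz[bad] <- 1; nrm[bad] <- 1
  cbind(vx / nrm, vy / nrm, vz / nrm)
}
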