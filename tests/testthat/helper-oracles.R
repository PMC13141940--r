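# Independent oracles, implemented before the code paths they check and
# kept free of any package internals.

# Horn's quaternion method: minimized RMSD and optimal proper rotation from
# the largest eigenvalue of the 4x4 key matrix (characteristic-polynomial
# route to the same quantity).
quaternionFit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- crossprod(P0, Q0)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  lambda <- e$values[1L]
  qv <- e$vectors[, 1L]
  w <- qv[1L]; x <- qv[2L]; y <- qv[3L]; z <- qv[4L]
  R <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
  msd <- (sum(P0^2) + sum(Q0^2) - 2*lambda) / n
  list(rmsd = sqrt(max(0, msd)), rotation = R)
}

# uniform random proper rotation via a random quaternion
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  t(matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE))
}

# analytic SASA of two intersecting spheres of radii r1, r2 (already
# solvent-expanded), centre distance d: each sphere loses a spherical cap.
twoSphereSASA <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4*pi*(r1^2 + r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2*d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2*d)
  (4*pi*r1^2 - 2*pi*r1*h1) + (4*pi*r2^2 - 2*pi*r2*h2)
}

# analytic form factor of a homogeneous sphere, normalized to 1 at q=0
sphereFormFactor <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# Debye function of a Gaussian chain (the canonical flexible/extended
# reference curve), I/I0 as a function of qRg
gaussianChainIntensity <- function(qrg) {
  x <- qrg^2
  ifelse(x < 1e-12, 1, 2 * (exp(-x) + x - 1) / x^2)
}
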