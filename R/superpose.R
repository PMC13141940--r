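#' @include AllClasses.R structio.R
NULL

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (default identity).
#' @param translation length-3 numeric (default zero).
#' @return a [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Rotation angle of a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return rotation angle in radians, in `[0, pi]`.
#' @export
rotationAngle <- function(t) {
  tr <- sum(diag(t@rotation))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  RigidTransform(Rt, -as.numeric(Rt %*% t@translation))
}

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` is the transform "apply b, then a".
#'
#' @param a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rigid motion (rotation + translation, no reflection)
#' minimizing the RMSD between the transformed mobile points and the target
#' points, via the SVD-based Kabsch algorithm with determinant sign
#' correction.
#'
#' @param mobile,target n x 3 coordinate matrices (or objects accepted by
#'   `as.matrix`), paired row by row, n >= 3.
#' @return a [SuperpositionResult-class] with the optimal transform, the
#'   minimized RMSD (Angstrom) and the pair count.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' rmsd(kabschFit(p, p))  # 0
#' @export
kabschFit <- function(mobile, target) {
  P <- as.matrix(mobile); Q <- as.matrix(target)
  storage.mode(P) <- storage.mode(Q) <- "double"
  if (ncol(P) != 3L || ncol(Q) != 3L) stop("coordinates must be n x 3")
  if (nrow(P) != nrow(Q))
    stop("pairing error: mobile and target must have the same number of points (",
         nrow(P), " vs ", nrow(Q), ")")
  n <- nrow(P)
  if (n < 3L) stop("conditioning error: at least 3 point pairs required")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  ## collinearity / degeneracy: two vanishing covariance singular values
  ## leave the rotation about the point axis undetermined
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], .Machine$double.eps))
    stop("conditioning error: degenerate (collinear or coincident) point sets")
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  moved <- P %*% t(R)
  moved <- sweep(moved, 2, tr, "+")
  rms <- sqrt(sum((moved - Q)^2) / n)
  new("SuperpositionResult",
      transform = RigidTransform(R, tr),
      rmsd = rms, nPairs = as.integer(n))
}

#' Apply a rigid transform to a structure
#'
#' Every atom position x is mapped to `R x + t`; all non-coordinate fields
#' are unchanged.
#'
#' @param model a [StructureModel-class].
#' @param t a [RigidTransform-class].
#' @return the transformed [StructureModel-class].
#' @export
applyTransform <- function(model, t) {
  stopifnot(is(t, "RigidTransform"))
  a <- atoms(model)
  if (nrow(a)) {
    xyz <- cbind(a$x, a$y, a$z) %*% t(t@rotation)
    xyz <- sweep(xyz, 2, t@translation, "+")
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  }
  .newStructureModel(a, identifier(model))
}

## Paired C-alpha coordinates of two chains, matched on author residue
## number + insertion code (intersection).
.pairedCA <- function(model1, chain1, model2, chain2) {
  ca1 <- atoms(selectAtoms(model1, chains = chain1, atomNames = "CA"))
  ca2 <- atoms(selectAtoms(model2, chains = chain2, atomNames = "CA"))
  k1 <- paste(ca1$resno, ca1$insert); k2 <- paste(ca2$resno, ca2$insert)
  common <- intersect(k1, k2)
  list(xyz1 = as.matrix(ca1[match(common, k1), c("x", "y", "z")]),
       xyz2 = as.matrix(ca2[match(common, k2), c("x", "y", "z")]),
       n = length(common))
}

#' Pairwise C-alpha RMSD of chains within a model
#'
#' For each chain in `otherChains`, pairs C-alpha atoms with `refChain` by
#' shared author residue number (the intersection), superposes them with
#' [kabschFit()] and reports the minimized RMSD.
#'
#' @param model a [StructureModel-class].
#' @param refChain reference chain id.
#' @param otherChains chain ids to compare; default all other chains.
#' @return named numeric vector of RMSDs (Angstrom).  A chain sharing fewer
#'   than 3 residues with the reference yields `NA` with a warning; the
#'   other chains are still returned.
#' @export
chainPairRMSD <- function(model, refChain, otherChains = NULL) {
  if (is.null(otherChains)) otherChains <- setdiff(chainIds(model), refChain)
  out <- setNames(rep(NA_real_, length(otherChains)), otherChains)
  for (ch in otherChains) {
    p <- .pairedCA(model, refChain, model, ch)
    if (p$n < 3L) {
      warning("pairing error: chains ", refChain, " and ", ch,
              " share fewer than 3 residue numbers")
      next
    }
    out[ch] <- rmsd(kabschFit(p$xyz1, p$xyz2))
  }
  out
}
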