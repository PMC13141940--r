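#' @include structio.R superpose.R saxs.R
NULL

## Synthetic generators with known ground truth.  They emulate the study
## system: an N-terminal two-helix protein fold with a bend, antiparallel
## coiled-coil dimers, uniformly filled spheres as analytic SAXS oracles,
## and a SEC elution series of scattering frames.

.axisAngle <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
}

.one2three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Generate an ideal alpha-helical backbone, optionally bent
#'
#' Places C-alpha atoms on an ideal helix (textbook parameters: 1.5
#' Angstrom rise, 100 degree twist, 2.3 Angstrom C-alpha radius) and adds
#' idealized backbone N, C and O pseudo-positions interpolated along the
#' trace.  When a bend is specified, the helix axis direction rotates by
#' `bendAngle` at `bendResidue` — emulating a two-helix fold with a bend,
#' as opposed to one elongated helix.  Deterministic.
#'
#' @param nResidues number of residues (>= 3).
#' @param rise rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param caRadius helix C-alpha radius (Angstrom).
#' @param bendResidue optional residue at which the axis bends
#'   (0 < bendResidue < nResidues).
#' @param bendAngle bend angle in degrees (required with `bendResidue`).
#' @param sequence optional one-letter amino-acid string of length
#'   `nResidues` (default poly-Ala).
#' @param chainId chain id (default "A").
#' @return a [StructureModel-class] with N, CA, C, O atoms per residue.
#' @examples
#' h <- makeHelix(10)
#' ca <- atoms(selectAtoms(h, atomNames = "CA"))
#' diff(ca$z)  # ~ constant rise along the axis
#' @export
makeHelix <- function(nResidues, rise = 1.5, twist = 100, caRadius = 2.3,
                      bendResidue = NULL, bendAngle = NULL, sequence = NULL,
                      chainId = "A") {
  if (nResidues < 3L) stop("invalid argument: nResidues must be >= 3")
  if (!is.null(bendResidue)) {
    if (bendResidue <= 0 || bendResidue >= nResidues)
      stop("invalid argument: bendResidue must satisfy 0 < bendResidue < nResidues")
    if (is.null(bendAngle)) stop("invalid argument: bendAngle required with bendResidue")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != nResidues)
      stop("invalid argument: sequence length must equal nResidues")
    res3 <- unname(.one2three[strsplit(sequence, "")[[1L]]])
    if (anyNA(res3)) stop("invalid argument: unknown amino-acid letter in sequence")
  } else res3 <- rep("ALA", nResidues)

  i <- seq_len(nResidues)
  th <- (i - 1) * twist * pi / 180
  ca <- cbind(caRadius * cos(th), caRadius * sin(th), (i - 1) * rise)
  ## pseudo backbone: N toward the previous CA, C toward the next
  dirPrev <- rbind(ca[1L, ] - ca[2L, ], ca[-nResidues, ] - ca[-1L, ])
  dirNext <- rbind(ca[-1L, ] - ca[-nResidues, ], ca[nResidues, ] - ca[nResidues - 1L, ])
  Npos <- ca + 0.25 * dirPrev
  Cpos <- ca + 0.25 * dirNext
  radial <- cbind(cos(th), sin(th), 0)
  Opos <- Cpos + 1.23 * radial
  if (!is.null(bendResidue) && bendAngle != 0) {
    R <- .axisAngle(c(1, 0, 0), bendAngle)
    pivot <- ca[bendResidue, ]
    bendPts <- function(m, rows) {
      m[rows, ] <- sweep(sweep(m[rows, , drop = FALSE], 2, pivot) %*% t(R),
                         2, pivot, "+")
      m
    }
    rows <- i > bendResidue
    ca <- bendPts(ca, rows); Npos <- bendPts(Npos, rows)
    Cpos <- bendPts(Cpos, rows); Opos <- bendPts(Opos, rows)
  }
  perRes <- function(resno) {
    data.frame(chain = chainId, resno = resno, resid = res3[resno],
               elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
               x = c(Npos[resno, 1], ca[resno, 1], Cpos[resno, 1], Opos[resno, 1]),
               y = c(Npos[resno, 2], ca[resno, 2], Cpos[resno, 2], Opos[resno, 2]),
               z = c(Npos[resno, 3], ca[resno, 3], Cpos[resno, 3], Opos[resno, 3]),
               stringsAsFactors = FALSE)
  }
  StructureModel(do.call(rbind, lapply(i, perRes)), identifier = "helix")
}

#' Generate an antiparallel two-helix dimer
#'
#' Chain A is an ideal (optionally bent) helix; chain B is chain A rotated
#' 180 degrees about an axis perpendicular to the helix axis (so the two
#' traces run antiparallel) and translated by `interhelixDistance`
#' perpendicular to the axis and `axialOffset` along it.  Deterministic.
#'
#' @inheritParams makeHelix
#' @param axialOffset shift of chain B along the helix axis (Angstrom).
#' @param interhelixDistance centre-to-centre separation (Angstrom, > 0).
#' @return a two-chain [StructureModel-class] (chains A and B).
#' @export
makeAntiparallelDimer <- function(nResidues, axialOffset = 0,
                                  interhelixDistance = 10, rise = 1.5,
                                  twist = 100, caRadius = 2.3,
                                  bendResidue = NULL, bendAngle = NULL,
                                  sequence = NULL) {
  if (interhelixDistance <= 0)
    stop("invalid argument: interhelixDistance must be > 0")
  a <- makeHelix(nResidues, rise, twist, caRadius, bendResidue, bendAngle,
                 sequence, chainId = "A")
  cenA <- colMeans(coords(a))
  R <- .axisAngle(c(1, 0, 0), 180)
  t <- as.numeric(cenA - R %*% cenA) + c(0, interhelixDistance, axialOffset)
  b <- applyTransform(a, RigidTransform(R, t))
  ab <- atoms(b); ab$chain <- "B"
  combineModels(a, .newStructureModel(ab), identifier = "antiparallel-dimer")
}

#' Generate a uniformly bead-filled sphere
#'
#' Beads are sampled uniformly in the ball by rejection sampling with a
#' fixed seed; each bead is a unit-weight pseudo-atom.  The analytic ground
#' truth `Rg = sqrt(3/5) * radius` and the sphere form factor make this the
#' oracle body for the scattering code.
#'
#' @param radius sphere radius (Angstrom).
#' @param nBeads number of beads (>= 100).
#' @param seed RNG seed (Mersenne-Twister via [set.seed()]).
#' @return a [StructureModel-class] (chain A, one CA pseudo-atom per bead).
#' @export
makeBeadSphere <- function(radius, nBeads, seed = 1) {
  if (nBeads < 100L) stop("invalid argument: nBeads must be >= 100")
  set.seed(seed)
  pts <- matrix(numeric(), 0, 3)
  while (nrow(pts) < nBeads) {
    cand <- matrix(stats::runif(3 * 2 * nBeads, -radius, radius), ncol = 3)
    cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(nBeads), , drop = FALSE]
  StructureModel(data.frame(chain = "A", resno = seq_len(nBeads),
                            resid = "GLY", elety = "CA", elesy = "C",
                            x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            stringsAsFactors = FALSE),
                 identifier = sprintf("bead-sphere-R%g", radius))
}

#' Generate a deterministic lattice-filled sphere
#'
#' Fills the ball of the given radius with points of a cubic lattice.
#' Unlike [makeBeadSphere()] this body has no Monte-Carlo sampling noise,
#' which makes it the oracle of choice when validating the Debye sum
#' against the analytic sphere form factor: any discrepancy is then due to
#' the scattering code, not to the body.
#'
#' @param radius sphere radius (Angstrom).
#' @param spacing lattice constant (Angstrom, default 1).
#' @return a [StructureModel-class] of unit-weight pseudo-atoms.
#' @export
makeLatticeSphere <- function(radius, spacing = 1) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  StructureModel(data.frame(chain = "A", resno = seq_len(nrow(pts)),
                            resid = "GLY", elety = "CA", elesy = "C",
                            x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            stringsAsFactors = FALSE),
                 identifier = sprintf("lattice-sphere-R%g", radius))
}

#' Simulate a SEC-SAXS elution frame series
#'
#' Frame i is `bufferLevel + gaussian(i; peakCenter, peakWidth) *
#' particleProfile`, plus optional relative Gaussian noise.  The defaults
#' emulate a synchrotron SEC-SAXS acquisition: 303 continuously collected
#' frames with the elution peak near frame 139, so that frames 1-15 precede
#' the sample fraction (background window) and frames 134-144 span the peak
#' (sample window).  The ground-truth amplitude trace is retained for
#' assertions.
#'
#' @param particleProfile a [ScatteringProfile-class] (the pure particle
#'   curve).
#' @param nFrames number of frames (default 303).
#' @param peakCenter,peakWidth Gaussian elution peak parameters (frames;
#'   defaults 139 and 4).
#' @param peakAmplitude amplitude of the elution peak (default 1).
#' @param bufferLevel constant buffer intensity added to every frame.
#' @param relSigma relative noise level (0 disables noise).
#' @param seed RNG seed.
#' @return a [FrameSeries-class]; `@groundTruth` holds `amplitude`,
#'   `bufferLevel` and the particle profile.
#' @export
simulateSECSeries <- function(particleProfile, nFrames = 303L,
                              peakCenter = 139, peakWidth = 4,
                              peakAmplitude = 1, bufferLevel = 0,
                              relSigma = 0, seed = 1) {
  if (nFrames <= peakCenter)
    stop("invalid argument: nFrames must exceed peakCenter")
  q <- particleProfile@q
  ip <- particleProfile@intensity
  amp <- peakAmplitude * exp(-((seq_len(nFrames) - peakCenter)^2) /
                               (2 * peakWidth^2))
  clean <- outer(ip, amp) + bufferLevel
  if (relSigma > 0) {
    set.seed(seed)
    sd <- relSigma * pmax(clean, bufferLevel, 0.01 * max(ip))
    noisy <- clean + matrix(stats::rnorm(length(clean), sd = sd), nrow(clean))
    sig <- sd
  } else {
    noisy <- clean
    sig <- matrix(numeric(), 0, 0)
  }
  new("FrameSeries", q = q, intensities = noisy, sigmas = sig,
      elutionIndex = seq_len(nFrames),
      groundTruth = list(amplitude = amp, bufferLevel = bufferLevel,
                         particle = particleProfile))
}

#' Perturb a structure by a rigid transform plus coordinate noise
#'
#' Applies the transform, then adds i.i.d. Gaussian noise of standard
#' deviation `coordinateSigma` to every coordinate axis of every atom
#' (fixed seed, reproducible).  With per-axis noise sigma the expected
#' minimized RMSD against the unperturbed model is `sigma * sqrt(3)`.
#'
#' @param model a [StructureModel-class].
#' @param transform a [RigidTransform-class] (default identity).
#' @param coordinateSigma per-axis noise standard deviation (Angstrom).
#' @param seed RNG seed.
#' @return the perturbed [StructureModel-class].
#' @export
perturbModel <- function(model, transform = RigidTransform(),
                         coordinateSigma = 0, seed = 1) {
  out <- applyTransform(model, transform)
  if (coordinateSigma > 0) {
    set.seed(seed)
    a <- atoms(out)
    n <- nrow(a)
    a$x <- a$x + stats::rnorm(n, sd = coordinateSigma)
    a$y <- a$y + stats::rnorm(n, sd = coordinateSigma)
    a$z <- a$z + stats::rnorm(n, sd = coordinateSigma)
    out <- .newStructureModel(a, identifier(model))
  }
  out
}

#' Fixture: an inter-chain ion pair at specified geometry
#'
#' Two single-residue chains — an arginine whose NH1 sits at the origin and
#' a glutamate whose OE1 sits at `(distance, 0, 0)` — so the minimum basic-N
#' to acidic-O separation is exactly `distance`.
#'
#' @param distance N-O distance (Angstrom).
#' @return a two-chain [StructureModel-class].
#' @export
makeSaltBridgePair <- function(distance) {
  StructureModel(data.frame(
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L),
    resid = c("ARG", "ARG", "GLU", "GLU"),
    elety = c("CA", "NH1", "CA", "OE1"),
    elesy = c("C", "N", "C", "O"),
    x = c(-4, 0, distance + 4, distance),
    y = 0, z = 0, stringsAsFactors = FALSE),
    identifier = "salt-bridge-pair")
}

#' Fixture: an inter-chain hydrophobic contact at specified geometry
#'
#' Two single-residue leucine chains whose CD1 side-chain carbons are
#' exactly `distance` apart.
#'
#' @param distance C-C distance (Angstrom).
#' @return a two-chain [StructureModel-class].
#' @export
makeHydrophobicPair <- function(distance) {
  StructureModel(data.frame(
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L),
    resid = "LEU",
    elety = c("CA", "CD1", "CA", "CD1"),
    elesy = "C",
    x = c(-4, 0, distance + 4, distance),
    y = 0, z = 0, stringsAsFactors = FALSE),
    identifier = "hydrophobic-pair")
}
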