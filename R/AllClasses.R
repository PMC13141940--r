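#' @import methods
NULL

## Atom records are held as a flat data.frame (one row per atom) with the
## columns below; hierarchical views (chains -> residues -> atoms) are
## derived by the accessors.  This mirrors the atom-table layout used by
## crystallographic toolkits and keeps file ordering trivially preserved.
.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "b", "alt")

#' StructureModel: a hierarchical atomic coordinate set
#'
#' Holds protein atoms (chains, author-numbered residues, atoms) with
#' coordinates in Angstrom.  Constructed by [readStructure()] or the
#' synthetic generators; a flat atom table is available via [atoms()].
#'
#' @slot identifier free-text identifier (e.g. a PDB accession).
#' @slot atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `elesy` (element), `x`, `y`, `z`, `o` (occupancy),
#'   `b` (B-factor), `alt` (altloc, "" once resolved).
#' @export
setClass("StructureModel",
         representation(identifier = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character()
  if (!all(.ATOM_COLS %in% names(a)))
    msgs <- c(msgs, paste("atom table must have columns:",
                          paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  if (nrow(a) > 0 && all(c("x", "y", "z", "o") %in% names(a))) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msgs <- c(msgs, "atom coordinates must be finite")
    if (any(!is.na(a$o) & (a$o < 0 | a$o > 1)))
      msgs <- c(msgs, "occupancy must lie in [0, 1]")
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    if (anyDuplicated(key))
      msgs <- c(msgs, "atom names must be unique within a residue after altloc resolution")
  }
  if (length(msgs)) msgs else TRUE
})

#' RigidTransform: a proper rigid-body motion
#'
#' Maps positions x to `rotation %*% x + translation`.  The rotation is a
#' proper rotation (orthonormal, determinant +1): reflections are excluded,
#' as required for physical superpositions of chiral molecules.
#'
#' @slot rotation 3x3 orthonormal matrix with det = +1.
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msgs <- character()
  if (!all(dim(R) == c(3, 3))) msgs <- c(msgs, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msgs <- c(msgs, "rotation must be orthonormal (R'R = I within 1e-8)")
    if (abs(det(R) - 1) > 1e-8)
      msgs <- c(msgs, "rotation must be proper (det = +1 within 1e-8)")
  }
  if (length(object@translation) != 3 || !all(is.finite(object@translation)))
    msgs <- c(msgs, "translation must be a finite 3-vector")
  if (length(msgs)) msgs else TRUE
})

#' SuperpositionResult: outcome of a least-squares rigid fit
#'
#' @slot transform the optimal [RigidTransform-class] mapping mobile onto
#'   target.
#' @slot rmsd minimized root-mean-square deviation (Angstrom).
#' @slot nPairs number of paired atoms used.
#' @export
setClass("SuperpositionResult",
         representation(transform = "RigidTransform", rmsd = "numeric",
                        nPairs = "integer"))

setValidity("SuperpositionResult", function(object) {
  msgs <- character()
  if (object@rmsd < 0) msgs <- c(msgs, "rmsd must be >= 0")
  if (object@nPairs < 3L) msgs <- c(msgs, "at least 3 paired atoms required")
  if (length(msgs)) msgs else TRUE
})

#' FilamentModel: a propagated oligomer with per-junction diagnostics
#'
#' @slot structure the assembled [StructureModel-class] (2 chains per dimer).
#' @slot nDimers number of dimer units.
#' @slot junctionReport data.frame with one row per inter-dimer junction:
#'   `junction`, `templatePair`, `fitRmsd` (Angstrom), `clashCount`
#'   (heavy-atom pairs closer than the clash cutoff between adjacent dimers).
#' @slot provenance data.frame mapping output chain ids to (copy index,
#'   source chain).
#' @export
setClass("FilamentModel",
         representation(structure = "StructureModel", nDimers = "integer",
                        junctionReport = "data.frame", provenance = "data.frame"))

setValidity("FilamentModel", function(object) {
  ch <- unique(object@structure@atoms$chain)
  msgs <- character()
  if (length(ch) != 2L * object@nDimers)
    msgs <- c(msgs, "chain count must equal 2 x nDimers")
  if (length(msgs)) msgs else TRUE
})

#' ScatteringProfile: a 1-D small-angle scattering curve
#'
#' @slot q momentum transfer, inverse Angstrom, strictly increasing, > 0
#'   (q = 0 is permitted as a leading point for theoretical curves).
#' @slot intensity scattered intensity (arbitrary or absolute units).
#' @slot sigma pointwise uncertainty; `numeric(0)` when absent.
#' @export
setClass("ScatteringProfile",
         representation(q = "numeric", intensity = "numeric", sigma = "numeric"))

setValidity("ScatteringProfile", function(object) {
  msgs <- character()
  if (length(object@q) != length(object@intensity))
    msgs <- c(msgs, "q and intensity must have equal length")
  if (length(object@sigma) && length(object@sigma) != length(object@q))
    msgs <- c(msgs, "sigma must be empty or match q in length")
  if (length(object@q)) {
    if (any(object@q < 0)) msgs <- c(msgs, "q must be non-negative")
    if (any(diff(object@q) <= 0)) msgs <- c(msgs, "q must be strictly increasing")
  }
  if (length(object@sigma) && any(object@sigma <= 0))
    msgs <- c(msgs, "sigma must be positive where present")
  if (length(msgs)) msgs else TRUE
})

#' FrameSeries: an elution series of scattering frames on a shared q grid
#'
#' @slot q shared momentum-transfer grid (inverse Angstrom).
#' @slot intensities matrix, one column per frame.
#' @slot sigmas matrix of the same shape (or 0x0 when absent).
#' @slot elutionIndex frame numbers.
#' @slot groundTruth list of generator metadata (empty for measured data).
#' @export
setClass("FrameSeries",
         representation(q = "numeric", intensities = "matrix",
                        sigmas = "matrix", elutionIndex = "integer",
                        groundTruth = "list"))

setValidity("FrameSeries", function(object) {
  msgs <- character()
  if (nrow(object@intensities) != length(object@q))
    msgs <- c(msgs, "intensity rows must match the q grid")
  if (ncol(object@intensities) != length(object@elutionIndex))
    msgs <- c(msgs, "one elution index per frame required")
  if (length(object@sigmas) &&
      !all(dim(object@sigmas) == dim(object@intensities)))
    msgs <- c(msgs, "sigmas must match intensities in shape")
  if (length(msgs)) msgs else TRUE
})

#' GuinierResult: outcome of a Guinier fit
#'
#' @slot rg radius of gyration (Angstrom).
#' @slot i0 forward intensity I(0).
#' @slot fitRange integer indices of the profile points used.
#' @slot qRgMax the dimensionless bound q*Rg applied to the fit window.
#' @slot rSquared coefficient of determination of the ln I vs q^2 fit.
#' @export
setClass("GuinierResult",
         representation(rg = "numeric", i0 = "numeric", fitRange = "integer",
                        qRgMax = "numeric", rSquared = "numeric"))

setValidity("GuinierResult", function(object) {
  msgs <- character()
  if (object@rg <= 0) msgs <- c(msgs, "rg must be positive")
  if (object@i0 <= 0) msgs <- c(msgs, "i0 must be positive")
  if (length(msgs)) msgs else TRUE
})

#' MsaAlignment: a loaded multiple sequence alignment
#'
#' @slot ids sequence identifiers (unique).
#' @slot seqs character matrix, one row per sequence, one column per
#'   alignment column; upper-case residues and "-" gaps.
#' @export
setClass("MsaAlignment",
         representation(ids = "character", seqs = "matrix"))

setValidity("MsaAlignment", function(object) {
  msgs <- character()
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "sequence ids must be unique")
  if (nrow(object@seqs) != length(object@ids))
    msgs <- c(msgs, "one matrix row per sequence id required")
  if (length(msgs)) msgs else TRUE
})

#' AlignmentColumnMap: reference residue number to alignment column mapping
#'
#' @slot referenceId the reference sequence name (e.g. "TurB").
#' @slot columnOfResidue named integer vector: names are reference residue
#'   numbers (ungapped positions counted from 1), values alignment columns.
#' @slot alignment the underlying [MsaAlignment-class].
#' @export
setClass("AlignmentColumnMap",
         representation(referenceId = "character",
                        columnOfResidue = "integer",
                        alignment = "MsaAlignment"))

setValidity("AlignmentColumnMap", function(object) {
  if (anyDuplicated(object@columnOfResidue))
    "column mapping must be injective" else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  ch <- unique(a$chain)
  cat(sprintf("StructureModel '%s': %d chain(s), %d residue(s), %d atom(s)\n",
              object@identifier, length(ch),
              length(unique(paste(a$chain, a$resno, a$insert))), nrow(a)))
  if (length(ch)) cat("  chains:", paste(ch, collapse = " "), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object)
  cat(sprintf("RigidTransform: rotation %.2f deg, translation |t| = %.3f A\n",
              ang * 180 / pi, sqrt(sum(object@translation^2))))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atom pairs\n",
              object@rmsd, object@nPairs))
})

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("ScatteringProfile: %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) ", with uncertainties" else ""))
})

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries: %d frames x %d q points\n",
              ncol(object@intensities), length(object@q)))
})

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf("GuinierResult: Rg %.2f A, I(0) %.4g, %d points (qRg <= %.2f), R^2 %.4f\n",
              object@rg, object@i0, length(object@fitRange), object@qRgMax,
              object@rSquared))
})

setMethod("show", "FilamentModel", function(object) {
  cat(sprintf("FilamentModel: %d dimers, %d chains, %d junction(s)\n",
              object@nDimers, length(unique(object@structure@atoms$chain)),
              nrow(object@junctionReport)))
})

setMethod("show", "MsaAlignment", function(object) {
  cat(sprintf("MsaAlignment: %d sequences x %d columns\n",
              length(object@ids), ncol(object@seqs)))
})

setMethod("show", "AlignmentColumnMap", function(object) {
  cat(sprintf("AlignmentColumnMap: reference '%s', %d residues mapped\n",
              object@referenceId, length(object@columnOfResidue)))
})
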