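#' @include structio.R
NULL

## van der Waals radii (Angstrom), a Bondi-type element table.  Used for
## both SASA and clash diagnostics.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98)

#' van der Waals radii used by the package
#'
#' @return named numeric vector of element radii (Angstrom).
#' @export
vdwRadii <- function() .VDW_RADII

.atomRadii <- function(a) {
  r <- .VDW_RADII[toupper(a$elesy)]
  if (any(is.na(r))) {
    bad <- unique(a$elesy[is.na(r)])
    stop("radius-lookup error: no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

## Deterministic golden-section spiral lattice of n points on the unit
## sphere.  No randomness: SASA is bit-reproducible for fixed n.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-section spiral point lattice.
#' For each atom, test points on the solvent-expanded sphere (vdW radius +
#' probe) are counted accessible when outside every neighbouring expanded
#' sphere; the atom area is the accessible fraction of its sphere area.
#'
#' @param model a [StructureModel-class].
#' @param probeRadius solvent probe radius (Angstrom, default 1.4).
#' @param nPoints test points per atom (default 960).
#' @return numeric vector of per-atom areas (Angstrom^2); `sum()` gives the
#'   molecular SASA.
#' @examples
#' one <- StructureModel(data.frame(chain = "A", resno = 1, resid = "ALA",
#'                                  elety = "CA", elesy = "C",
#'                                  x = 0, y = 0, z = 0))
#' sum(computeSASA(one))           # ~ 4*pi*(1.7 + 1.4)^2
#' @export
computeSASA <- function(model, probeRadius = 1.4, nPoints = 960) {
  a <- atoms(model)
  n <- nrow(a)
  if (!n) return(numeric())
  rad <- .atomRadii(a) + probeRadius
  xyz <- cbind(a$x, a$y, a$z)
  pts <- .spherePoints(nPoints)
  ## neighbour lists via a cell grid to avoid the full distance matrix
  maxR <- max(rad)
  cell <- 2 * maxR
  key <- paste(floor(xyz[, 1] / cell), floor(xyz[, 2] / cell),
               floor(xyz[, 3] / cell))
  cells <- split(seq_len(n), key)
  coord <- floor(xyz / cell)
  area <- numeric(n)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(n)) {
    cand <- unlist(cells[paste(coord[i, 1] + offsets[, 1],
                               coord[i, 2] + offsets[, 2],
                               coord[i, 3] + offsets[, 3])],
                   use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (rad[i] + rad[cand])^2 & d2 > 0]
    }
    if (!length(cand)) { area[i] <- 4 * pi * rad[i]^2; next }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (jj in cand) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[jj, 1])^2 + (p[free, 2] - xyz[jj, 2])^2 +
        (p[free, 3] - xyz[jj, 3])^2
      free[free] <- d2 >= rad[jj]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / nPoints
  }
  area
}

#' Buried interface area between two chains
#'
#' PISA-style interface area: `(SASA(chain1 alone) + SASA(chain2 alone) -
#' SASA(both chains)) / 2`.  When `residueRange` is given, the per-atom
#' areas are summed over atoms of residues in that range only (the SASA
#' itself is always computed in the full one- or two-chain context).
#'
#' @param model a [StructureModel-class] containing both chains.
#' @param chain1,chain2 chain ids.
#' @param residueRange optional inclusive residue-number interval.
#' @param probeRadius,nPoints passed to [computeSASA()].
#' @return buried area in Angstrom^2 (>= 0; 0 for disjoint chains).
#' @export
interfaceArea <- function(model, chain1, chain2, residueRange = NULL,
                          probeRadius = 1.4, nPoints = 960) {
  m1 <- selectAtoms(model, chains = chain1)
  m2 <- selectAtoms(model, chains = chain2)
  if (!nAtoms(m1) || !nAtoms(m2))
    stop("both chains must be present in the model")
  both <- combineModels(m1, m2, identifier = "pair")
  inRange <- function(m) {
    if (is.null(residueRange)) rep(TRUE, nAtoms(m))
    else atoms(m)$resno >= residueRange[1L] & atoms(m)$resno <= residueRange[2L]
  }
  s1 <- sum(computeSASA(m1, probeRadius, nPoints)[inRange(m1)])
  s2 <- sum(computeSASA(m2, probeRadius, nPoints)[inRange(m2)])
  s12 <- sum(computeSASA(both, probeRadius, nPoints)[inRange(both)])
  max(0, (s1 + s2 - s12) / 2)
}

## side-chain atom sets for charged-group detection
.BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                 HIS = c("ND1", "NE2"))
.ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.APOLAR_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

.minPairRecords <- function(a1, a2, cutoff, kind) {
  ## all inter-set atom pairs within cutoff, reduced to one record per
  ## residue pair keeping the minimum distance
  if (!nrow(a1) || !nrow(a2)) return(.emptyRecords())
  d2 <- outer(a1$x^2 + a1$y^2 + a1$z^2, a2$x^2 + a2$y^2 + a2$z^2, "+") -
    2 * (cbind(a1$x, a1$y, a1$z) %*% t(cbind(a2$x, a2$y, a2$z)))
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(.emptyRecords())
  rec <- data.frame(kind = kind,
                    chain1 = a1$chain[hit[, 1]], residue1 = a1$resno[hit[, 1]],
                    resname1 = a1$resid[hit[, 1]], atom1 = a1$elety[hit[, 1]],
                    chain2 = a2$chain[hit[, 2]], residue2 = a2$resno[hit[, 2]],
                    resname2 = a2$resid[hit[, 2]], atom2 = a2$elety[hit[, 2]],
                    distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
  rec <- rec[rec$chain1 != rec$chain2, ]
  if (!nrow(rec)) return(.emptyRecords())
  key <- paste(rec$chain1, rec$residue1, rec$chain2, rec$residue2)
  rec <- rec[order(key, rec$distance), ]
  rec <- rec[!duplicated(paste(rec$chain1, rec$residue1, rec$chain2, rec$residue2)), ]
  rownames(rec) <- NULL
  rec
}

.emptyRecords <- function()
  data.frame(kind = character(), chain1 = character(), residue1 = integer(),
             resname1 = character(), atom1 = character(), chain2 = character(),
             residue2 = integer(), resname2 = character(), atom2 = character(),
             distance = numeric(), stringsAsFactors = FALSE)

## canonical chain order so detection is symmetric in chain labelling
.orientRecords <- function(rec) {
  if (!nrow(rec)) return(rec)
  swap <- rec$chain1 > rec$chain2
  if (any(swap)) {
    tmp <- rec[swap, c("chain2", "residue2", "resname2", "atom2")]
    rec[swap, c("chain2", "residue2", "resname2", "atom2")] <-
      rec[swap, c("chain1", "residue1", "resname1", "atom1")]
    rec[swap, c("chain1", "residue1", "resname1", "atom1")] <- tmp
  }
  ## a symmetric atom-set self-join reports each residue pair twice;
  ## keep the closest record per oriented pair
  rec <- rec[order(rec$chain1, rec$residue1, rec$chain2, rec$residue2,
                   rec$distance), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$chain1, rec$residue1, rec$chain2,
                               rec$residue2)), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Detect inter-chain salt bridges
#'
#' A salt bridge is recorded when a basic side-chain nitrogen (Arg NE/NH1/
#' NH2; Lys NZ; optionally His ND1/NE2) lies within `cutoff` of an acidic
#' side-chain oxygen (Asp OD1/OD2; Glu OE1/OE2) on a different chain.  One
#' record per residue pair is kept, at the minimum N-O distance.
#'
#' @param model a [StructureModel-class].
#' @param cutoff N-O distance threshold (Angstrom, default 4.0).
#' @param includeHis treat His as basic (default FALSE).
#' @return data.frame of interaction records (kind `"salt_bridge"`), with
#'   chain/residue/atom identities and the distance.
#' @export
findSaltBridges <- function(model, cutoff = 4.0, includeHis = FALSE) {
  a <- atoms(model)
  basics <- .BASIC_N
  if (!includeHis) basics$HIS <- NULL
  isBasic <- mapply(function(res, at) a$resid == res & a$elety %in% at,
                    names(basics), basics, SIMPLIFY = FALSE)
  isAcid <- mapply(function(res, at) a$resid == res & a$elety %in% at,
                   names(.ACIDIC_O), .ACIDIC_O, SIMPLIFY = FALSE)
  aN <- a[Reduce(`|`, isBasic), ]
  aO <- a[Reduce(`|`, isAcid), ]
  .orientRecords(.minPairRecords(aN, aO, cutoff, "salt_bridge"))
}

#' Detect inter-chain hydrophobic contacts
#'
#' Contacts between apolar atoms: side-chain carbons of Ala, Val, Leu, Ile,
#' Met, Phe, Trp, Pro, plus the C-alpha of Gly (glycine has no side chain,
#' yet packs through its exposed alpha-carbon).  One record per residue pair
#' (minimum C-C distance); the participating residue set per chain lists
#' every residue with at least one contact.
#'
#' @param model a [StructureModel-class].
#' @param cutoff C-C distance threshold (Angstrom, default 4.5).
#' @return list with `records` (data.frame, kind `"hydrophobic"`) and
#'   `participating` (named list: chain id -> sorted residue numbers).
#' @export
findHydrophobicContacts <- function(model, cutoff = 4.5) {
  a <- atoms(model)
  backbone <- c("N", "CA", "C", "O", "OXT")
  apolar <- (a$resid %in% .APOLAR_RES & a$elesy == "C" & !(a$elety %in% backbone)) |
    (a$resid == "GLY" & a$elety == "CA")
  aa <- a[apolar, ]
  rec <- .orientRecords(.minPairRecords(aa, aa, cutoff, "hydrophobic"))
  part <- list()
  for (ch in unique(c(rec$chain1, rec$chain2)))
    part[[ch]] <- sort(unique(c(rec$residue1[rec$chain1 == ch],
                                rec$residue2[rec$chain2 == ch])))
  list(records = rec, participating = part)
}

#' Characterize dimer interfaces
#'
#' For each chain pair: buried interface area (optionally restricted to a
#' residue range), the full-chain buried area, inter-chain salt bridges and
#' the hydrophobic participating residue set.
#'
#' @param model a [StructureModel-class].
#' @param pairs list of `c(chain1, chain2)` pairs.
#' @param residueRange optional inclusive residue interval for the area
#'   restriction.
#' @param saltCutoff,hydroCutoff detection cutoffs (Angstrom).
#' @param probeRadius,nPoints passed to [computeSASA()].
#' @return list of per-pair reports; each has `chainPair`, `buriedArea`,
#'   `buriedAreaFullChain`, `residueRangeUsed`, `saltBridges` (data.frame)
#'   and `hydrophobicResidues` (named list per chain).
#' @export
dimerReport <- function(model, pairs, residueRange = NULL,
                        saltCutoff = 4.0, hydroCutoff = 4.5,
                        probeRadius = 1.4, nPoints = 960) {
  lapply(pairs, function(pr) {
    sub <- selectAtoms(model, chains = pr)
    sb <- findSaltBridges(sub, cutoff = saltCutoff)
    hc <- findHydrophobicContacts(sub, cutoff = hydroCutoff)
    list(chainPair = pr,
         buriedArea = interfaceArea(model, pr[1L], pr[2L], residueRange,
                                    probeRadius, nPoints),
         buriedAreaFullChain = interfaceArea(model, pr[1L], pr[2L], NULL,
                                             probeRadius, nPoints),
         residueRangeUsed = residueRange,
         saltBridges = sb,
         hydrophobicResidues = hc$participating)
  })
}

#' Write interaction records as TSV
#'
#' @param records data.frame from [findSaltBridges()] or
#'   [findHydrophobicContacts()]`$records`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeInteractionRecords <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
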