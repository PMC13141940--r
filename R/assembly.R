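#' @include superpose.R
NULL

## Assembly: the model-building route for the native oligomerization domain.
## A chimeric monomer is spliced from two donor crystal structures (the bent
## terminal-dimerization-site fold supplies the N-terminal part, the
## central-dimerization-site dimer supplies the C-terminal part), two
## chimeras inherit the central dimer geometry, and the filament is grown by
## repeatedly superposing dimer copies onto the crystal's terminal-dimer
## template.

.chainOf <- function(model, chain) selectAtoms(model, chains = chain)

#' Splice a chimeric monomer from two donor structures
#'
#' Superposes the N-terminal donor chain onto the C-terminal donor chain via
#' the C-alpha atoms of `fitRange` ([kabschFit()]), then concatenates the
#' transformed `nRange` residues of the N donor with the `cRange` residues of
#' the C donor into a single chain.  Author residue numbering is kept, so the
#' two ranges must be disjoint and contiguous (`max(nRange) + 1 ==
#' min(cRange)`).  The junction is diagnosed, not regularized: the C(i)-N(i+1)
#' peptide-bond distance across the junction is reported and flagged when
#' outside [1.0, 2.0] Angstrom.
#'
#' @param nDonor,cDonor donor [StructureModel-class] objects.
#' @param nChain,cChain donor chain ids.
#' @param fitRange inclusive residue range used for the superposition
#'   (default 32-49, the shared central-site helix).
#' @param nRange inclusive residues taken from the N donor (default 2-32).
#' @param cRange inclusive residues taken from the C donor (default 33-58).
#' @param outChain chain id of the chimera (default "A").
#' @return list with `model` (single-chain [StructureModel-class]),
#'   `fitRmsd` (Angstrom), `junctionDistance` (C-N distance, `NA` if the
#'   backbone atoms are missing) and `junctionFlagged` (logical).
#' @export
spliceChimera <- function(nDonor, nChain, cDonor, cChain,
                          fitRange = c(32, 49), nRange = c(2, 32),
                          cRange = c(33, 58), outChain = "A") {
  if (max(nRange) >= min(cRange))
    stop("invalid argument: nRange and cRange must be disjoint")
  if (max(nRange) + 1L != min(cRange))
    stop("invalid argument: junction must be contiguous (max(nRange) + 1 == min(cRange))")
  caN <- atoms(selectAtoms(nDonor, chains = nChain, residues = fitRange,
                           atomNames = "CA"))
  caC <- atoms(selectAtoms(cDonor, chains = cChain, residues = fitRange,
                           atomNames = "CA"))
  common <- intersect(paste(caN$resno, caN$insert), paste(caC$resno, caC$insert))
  if (length(common) < 3L)
    stop("conditioning error: fewer than 3 shared C-alpha atoms in fitRange")
  m1 <- as.matrix(caN[match(common, paste(caN$resno, caN$insert)), c("x", "y", "z")])
  m2 <- as.matrix(caC[match(common, paste(caC$resno, caC$insert)), c("x", "y", "z")])
  fit <- kabschFit(m1, m2)
  nPart <- applyTransform(selectAtoms(nDonor, chains = nChain, residues = nRange),
                          fitTransform(fit))
  cPart <- selectAtoms(cDonor, chains = cChain, residues = cRange)
  an <- atoms(nPart); ac <- atoms(cPart)
  an$chain <- outChain; ac$chain <- outChain
  model <- .newStructureModel(rbind(an, ac), "chimera")
  cAtom <- an[an$resno == max(nRange) & an$elety == "C", ]
  nAtom <- ac[ac$resno == min(cRange) & ac$elety == "N", ]
  if (nrow(cAtom) == 1L && nrow(nAtom) == 1L) {
    jd <- sqrt((cAtom$x - nAtom$x)^2 + (cAtom$y - nAtom$y)^2 + (cAtom$z - nAtom$z)^2)
  } else {
    warning("junction backbone atoms missing; junction distance omitted")
    jd <- NA_real_
  }
  list(model = model, fitRmsd = rmsd(fit), junctionDistance = jd,
       junctionFlagged = is.finite(jd) && (jd < 1.0 || jd > 2.0))
}

#' Assemble the central-site dimer from two chimeras
#'
#' Both chimeras keep their C-donor coordinates fixed, so their mutual
#' placement is inherited from the C-donor dimer frame: no additional
#' fitting is performed here.  Exact coordinate duplication (the same chain
#' passed twice) is an error, since it can only produce a fully clashed
#' non-physical dimer.
#'
#' @param chimera1,chimera2 single-chain [StructureModel-class] objects.
#' @param ids output chain ids (default A and B); collisions are resolved
#'   with a message.
#' @return a two-chain [StructureModel-class].
#' @export
buildCentralDimer <- function(chimera1, chimera2, ids = c("A", "B")) {
  a1 <- atoms(chimera1); a2 <- atoms(chimera2)
  if (nrow(a1) == nrow(a2) &&
      isTRUE(all.equal(a1[, c("x", "y", "z")], a2[, c("x", "y", "z")],
                       tolerance = 0, check.attributes = FALSE))) {
    cl <- .clashCount(as.matrix(a1[, c("x", "y", "z")]),
                      as.matrix(a2[, c("x", "y", "z")]), 2.4)
    stop("exact coordinate duplication: the two chimeras are identical (",
         cl, " clashing atom pairs)")
  }
  a1$chain <- ids[1L]; a2$chain <- ids[2L]
  combineModels(.newStructureModel(a1), .newStructureModel(a2),
                identifier = "central-dimer")
}

#' Propagate a filament through the terminal-dimerization template
#'
#' Grows an oligomer from a central-site dimer by iteratively placing copies
#' of it: at each junction the crystal terminal-dimer template is aligned
#' (via the C-alpha atoms of `fitRange`) onto the current growing-end chain,
#' the partner chain of the template defines the docking frame, and a dimer
#' copy is superposed onto that frame with its corresponding chain.  The
#' growing end alternates between the two dimer chains (each monomer
#' contributes one terminal site), and the template pairs in `templatePairs`
#' are used cyclically, mirroring the use of both crystal terminal dimers.
#'
#' @param dimer two-chain [StructureModel-class] (the repeating unit).
#' @param template [StructureModel-class] containing the terminal-dimer
#'   chains referenced by `templatePairs`.
#' @param templatePairs list of `c(chain, partnerChain)` pairs, cycled along
#'   the filament (default `list(c("A","G"), c("F","B"))`).
#' @param fitRange inclusive residue interval of the terminal-site helix used
#'   for every superposition (default 2-27).
#' @param nDimers number of dimer units in the result (>= 1).
#' @param clashCutoff heavy-atom clash threshold between adjacent dimers
#'   (Angstrom, default 2.4).
#' @return a [FilamentModel-class]: the assembled structure with chains
#'   renamed sequentially (A, B, C, ...), the per-junction report
#'   (template/copy fit RMSDs and clash counts) and a chain provenance map.
#' @export
propagateFilament <- function(dimer, template,
                              templatePairs = list(c("A", "G"), c("F", "B")),
                              fitRange = c(2, 27), nDimers,
                              clashCutoff = 2.4) {
  if (missing(nDimers) || nDimers < 1L)
    stop("invalid argument: nDimers must be >= 1")
  nDimers <- as.integer(nDimers)
  dch <- chainIds(dimer)
  if (length(dch) != 2L) stop("dimer must have exactly two chains")
  pool <- c(LETTERS, letters, as.character(0:9))
  if (2L * nDimers > length(pool))
    stop("chain-id exhaustion: at most ", length(pool) %/% 2L, " dimers supported")

  rename <- function(m, map) {
    a <- atoms(m)
    a$chain <- unname(map[a$chain])
    .newStructureModel(a, identifier(m))
  }
  outMap <- setNames(pool[1:2], dch)
  placed <- list(rename(dimer, outMap))
  prov <- data.frame(outChain = pool[1:2], copy = 1L, sourceChain = dch,
                     stringsAsFactors = FALSE)
  junctions <- data.frame(junction = integer(), templatePair = character(),
                          templateRmsd = numeric(), fitRmsd = numeric(),
                          clashCount = integer(), stringsAsFactors = FALSE)
  endIdx <- 1L                      # which dimer chain carries the free end
  endChain <- pool[endIdx]          # its id in the output
  status <- "complete"
  if (nDimers > 1L) for (j in seq_len(nDimers - 1L)) {
    pair <- templatePairs[[(j - 1L) %% length(templatePairs) + 1L]]
    res <- tryCatch({
      prev <- placed[[length(placed)]]
      ## template chain pair[1] -> current growing end
      p1 <- .pairedCA(.restrictRange(template, pair[1L], fitRange), pair[1L],
                      .restrictRange(prev, endChain, fitRange), endChain)
      if (p1$n < 3L) stop("conditioning error: template/end share < 3 residues")
      f1 <- kabschFit(p1$xyz1, p1$xyz2)
      mappedQ <- applyTransform(
        selectAtoms(template, chains = pair[2L], residues = fitRange,
                    atomNames = "CA"), fitTransform(f1))
      ## dimer copy: align its end-side chain onto the mapped partner
      p2 <- .pairedCA(.restrictRange(dimer, dch[endIdx], fitRange), dch[endIdx],
                      mappedQ, pair[2L])
      if (p2$n < 3L) stop("conditioning error: copy/template share < 3 residues")
      f2 <- kabschFit(p2$xyz1, p2$xyz2)
      copy <- applyTransform(dimer, fitTransform(f2))
      newIds <- pool[(2L * j + 1L):(2L * j + 2L)]
      copyMap <- setNames(newIds, dch)
      copyOut <- rename(copy, copyMap)
      cl <- .clashCount(coords(copyOut), coords(prev), clashCutoff)
      list(copyOut = copyOut, copyMap = copyMap, f1 = f1, f2 = f2, clash = cl,
           newIds = newIds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("propagation stopped at junction ", j, ": ", conditionMessage(res))
      status <- "partial"
      break
    }
    placed[[length(placed) + 1L]] <- res$copyOut
    prov <- rbind(prov, data.frame(outChain = res$newIds, copy = j + 1L,
                                   sourceChain = dch, stringsAsFactors = FALSE))
    junctions <- rbind(junctions, data.frame(
      junction = j, templatePair = paste(pair, collapse = "-"),
      templateRmsd = rmsd(res$f1), fitRmsd = rmsd(res$f2),
      clashCount = as.integer(res$clash), stringsAsFactors = FALSE))
    endIdx <- 3L - endIdx
    endChain <- res$copyMap[[dch[endIdx]]]
  }
  structure <- .newStructureModel(do.call(rbind, lapply(placed, atoms)),
                                  "filament")
  out <- new("FilamentModel", structure = structure,
             nDimers = length(placed), junctionReport = junctions,
             provenance = prov)
  attr(out, "status") <- status
  out
}

## chain sub-structure restricted to a residue range (internal)
.restrictRange <- function(model, chain, range)
  selectAtoms(model, chains = chain, residues = range)

#' Write a filament junction report as JSON lines
#'
#' One JSON record per junction with the fit RMSDs and clash count.
#'
#' @param filament a [FilamentModel-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeJunctionReport <- function(filament, path) {
  jr <- junctionReport(filament)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(jr)))
    writeLines(jsonlite::toJSON(as.list(jr[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
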