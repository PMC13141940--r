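#' @include AllClasses.R
NULL

## 3-letter codes accepted as polymer protein residues (20 standard plus
## common modified residues kept as protein).
.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "MSE","SEC","PYL","UNK")

.newStructureModel <- function(atoms, identifier = "") {
  rownames(atoms) <- NULL
  new("StructureModel", identifier = as.character(identifier), atoms = atoms)
}

#' Build a StructureModel from an atom table
#'
#' Low-level constructor used by the generators and tests.  Missing optional
#' columns (`insert`, `o`, `b`, `alt`, `elesy`) are filled with defaults;
#' `elesy` is inferred from the first letter of the atom name when absent.
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param identifier free-text identifier.
#' @return a [StructureModel-class].
#' @export
StructureModel <- function(atoms, identifier = "") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(gsub("[^A-Za-z].*", "", atoms$elety), 1, 1)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  .newStructureModel(atoms[, .ATOM_COLS], identifier)
}

.resolveAltlocs <- function(a) {
  a$alt[is.na(a$alt)] <- ""
  if (!any(a$alt != "")) return(a)
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- a[idx, ]
    hit <- which(sub$alt == "A")
    if (!length(hit)) {
      occ <- ifelse(is.na(sub$o), 0, sub$o)
      hit <- which(occ == max(occ))
    }
    idx[hit[1L]]
  }), use.names = FALSE)
  a <- a[sort(keep), ]
  a$alt <- ""
  a
}

.guessFormat <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.(cif|mmcif)$", p)) "mmcif" else "pdb"
}

.maybeGunzip <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  tmp <- tempfile(fileext = sub("\\.gz$", "", paste0("_", basename(path))))
  writeLines(readLines(gzfile(path)), tmp)
  tmp
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses a coordinate file (optionally gzip-compressed) and returns the
#' polymer protein atoms only: waters, heteroatoms and hydrogens are
#' excluded, alternate locations are resolved (altloc "A", else highest
#' occupancy, ties to the first record in the file), and chain/residue
#' ordering is preserved from the file.  Author (auth_) chain letters and
#' residue numbers are used throughout.  For multi-model (NMR-style) files
#' only the first model is read.
#'
#' @param path file path; `.gz` accepted.
#' @param format `"auto"` (from extension), `"pdb"`, or `"mmcif"`.
#' @param identifier identifier stored on the model; defaults to the file
#'   base name.
#' @return a [StructureModel-class].
#' @examples
#' m <- makeHelix(5)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(m, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guessFormat(path)
  if (is.null(identifier))
    identifier <- sub("\\.(pdb|cif|mmcif)(\\.gz)?$", "", basename(path),
                      ignore.case = TRUE)
  local <- .maybeGunzip(path)
  parsed <- tryCatch(
    withCallingHandlers(
      if (format == "pdb") bio3d::read.pdb(local, multi = FALSE, rm.alt = FALSE,
                                           verbose = FALSE)
      else bio3d::read.cif(local, rm.alt = FALSE, verbose = FALSE),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) {
      ln <- tryCatch(readLines(local, warn = FALSE), error = function(e2) character())
      bad <- which(!grepl("^(ATOM|HETATM|TER|END|MODEL|ENDMDL|ANISOU|REMARK|HEADER|TITLE|COMPND|SOURCE|SEQRES|CRYST1|SCALE|ORIGX|EXPDTA|AUTHOR|REVDAT|JRNL|DBREF|SEQADV|HELIX|SHEET|SSBOND|LINK|CONECT|MASTER|HET|FORMUL|#|_|data_|loop_|;)", ln) & nzchar(ln))
      stop("cannot parse '", path, "' as ", format,
           if (length(bad)) paste0(": first offending line ", bad[1L], ": '",
                                   substr(ln[bad[1L]], 1, 40), "'")
           else paste0(": ", conditionMessage(e)), call. = FALSE)
    })
  a <- parsed$atom
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- ""
  ## polymer protein only; drop waters, ligands and hydrogens
  keep <- a$type == "ATOM" & a$resid %in% .AA3
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 substr(gsub("^[0-9]*", "", a$elety), 1, 1), a$elesy)
  keep <- keep & !(toupper(elem) %in% c("H", "D"))
  a <- a[keep, ]
  if (!nrow(a))
    stop("empty structure: '", path, "' contains no polymer protein atoms")
  if (any(a$insert != ""))
    warning("insertion codes present in '", path, "'; kept verbatim")
  a <- .resolveAltlocs(a)
  out <- data.frame(chain = as.character(a$chain), resno = as.integer(a$resno),
                    insert = as.character(a$insert), resid = as.character(a$resid),
                    elety = as.character(a$elety),
                    elesy = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                                           substr(gsub("^[0-9]*", "", a$elety), 1, 1),
                                           a$elesy)),
                    x = a$x, y = a$y, z = a$z,
                    o = ifelse(is.na(a$o), 1, pmin(pmax(a$o, 0), 1)),
                    b = ifelse(is.na(a$b), 0, a$b),
                    alt = "", stringsAsFactors = FALSE)
  .newStructureModel(out, identifier)
}

#' Write a StructureModel as a PDB file
#'
#' Emits standard ATOM/TER/END records (wwPDB v3.3 columns).  A model
#' written and re-read round-trips chain ids, residue numbers and names,
#' atom names and coordinates to 3 decimal places.
#'
#' @param model a [StructureModel-class]; must be non-empty.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  if (!nrow(a)) stop("cannot write an empty structure")
  if (length(unique(a$chain)) > 62L)
    stop("chain-id exhaustion: PDB format supports at most 62 chains")
  if (any(a$resno > 9999L | a$resno < -999L))
    stop("residue numbers outside [-999, 9999] cannot be represented in PDB format")
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(cbind(a$x, a$y, a$z))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Select a sub-structure
#'
#' Filters a structure by chain ids, an inclusive author residue-number
#' range, and/or atom names.  All given filters must match; atom ordering
#' is preserved.  An empty selection is a valid value, not an error.
#'
#' @param model a [StructureModel-class].
#' @param chains optional character vector of chain ids.
#' @param residues optional inclusive range `c(lo, hi)` of author residue
#'   numbers.
#' @param atomNames optional character vector of atom names (e.g. `"CA"`).
#' @return a [StructureModel-class] (possibly with zero atoms).
#' @examples
#' m <- makeHelix(10)
#' nAtoms(selectAtoms(m, residues = c(2, 5), atomNames = "CA"))  # 4
#' @export
selectAtoms <- function(model, chains = NULL, residues = NULL, atomNames = NULL) {
  a <- atoms(model)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% as.character(chains)
  if (!is.null(residues)) {
    if (length(residues) != 2L || residues[1L] > residues[2L])
      stop("residues must be an inclusive range c(lo, hi)")
    keep <- keep & a$resno >= residues[1L] & a$resno <= residues[2L]
  }
  if (!is.null(atomNames)) keep <- keep & a$elety %in% atomNames
  .newStructureModel(a[keep, ], identifier(model))
}

#' Combine structures into one model with distinct chain ids
#'
#' Chains keep their ids where possible; on collision the incoming chain is
#' renamed to the next free id in A-Z, a-z, 0-9 and a message is emitted.
#'
#' @param ... StructureModel objects.
#' @param identifier identifier for the combined model.
#' @return a [StructureModel-class].
#' @export
combineModels <- function(..., identifier = "combined") {
  mods <- list(...)
  pool <- c(LETTERS, letters, 0:9)
  used <- character()
  pieces <- list()
  for (m in mods) {
    a <- atoms(m)
    for (ch in unique(a$chain)) {
      sub <- a[a$chain == ch, ]
      if (ch %in% used) {
        newId <- setdiff(pool, used)[1L]
        if (is.na(newId)) stop("chain-id exhaustion while combining models")
        message("chain id '", ch, "' already in use; renamed to '", newId, "'")
        sub$chain <- newId
        ch <- newId
      }
      used <- c(used, ch)
      pieces[[length(pieces) + 1L]] <- sub
    }
  }
  .newStructureModel(do.call(rbind, pieces), identifier)
}

## pairwise heavy-atom clash count between two atom subsets
.clashCount <- function(xyz1, xyz2, cutoff) {
  if (!nrow(xyz1) || !nrow(xyz2)) return(0L)
  n <- 0L
  ## block over the first set to bound memory
  step <- max(1L, floor(2e6 / nrow(xyz2)))
  for (s in seq(1L, nrow(xyz1), by = step)) {
    idx <- s:min(s + step - 1L, nrow(xyz1))
    d2 <- outer(rowSums(xyz1[idx, , drop = FALSE]^2), rowSums(xyz2^2), "+") -
      2 * tcrossprod(xyz1[idx, , drop = FALSE], xyz2)
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

#' Count steric clashes between two chain groups
#'
#' Heavy-atom pairs closer than `cutoff` between the two groups.
#'
#' @param model a [StructureModel-class].
#' @param chains1,chains2 chain id vectors (disjoint).
#' @param cutoff distance threshold in Angstrom (default 2.4, a conservative
#'   van der Waals overlap criterion).
#' @return integer clash count.
#' @export
countClashes <- function(model, chains1, chains2, cutoff = 2.4) {
  a <- atoms(model)
  .clashCount(as.matrix(a[a$chain %in% chains1, c("x", "y", "z")]),
              as.matrix(a[a$chain %in% chains2, c("x", "y", "z")]),
              cutoff)
}
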