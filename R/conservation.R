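#' @include AllClasses.R
NULL

#' Default amino-acid similarity groups
#'
#' Side-chain classes used to call residues "similar": aliphatic/small
#' `ILVMA`, aromatic `FWY`, basic `KRH`, acidic `DE`, polar `STNQ`,
#' conformationally special `GP`, and cysteine alone.
#'
#' @return named list of character vectors of one-letter codes.
#' @export
defaultSimilarityGroups <- function() {
  list(aliphatic = c("I", "L", "V", "M", "A"),
       aromatic = c("F", "W", "Y"),
       basic = c("K", "R", "H"),
       acidic = c("D", "E"),
       polar = c("S", "T", "N", "Q"),
       special = c("G", "P"),
       cysteine = "C")
}

#' Load a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file (via Biostrings); any Clustal
#' conservation line is ignored.  All sequences must have the same aligned
#' length and unique ids.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"fasta"` or `"clustal"`.
#' @return an [MsaAlignment-class].
#' @export
loadAlignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- sub("[[:space:]].*", "", names(ss))
    w <- Biostrings::width(ss)
    if (length(unique(w)) > 1L) {
      bad <- ids[which(w != w[1L])[1L]]
      stop("ragged alignment: sequence '", bad, "' has length ", w[w != w[1L]][1L],
           ", expected ", w[1L])
    }
    seqs <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  } else {
    aln <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                    error = function(e)
                      stop("cannot parse '", path, "' as clustal: ",
                           conditionMessage(e), call. = FALSE))
    aa <- as.character(Biostrings::unmasked(aln))
    ids <- names(aa)
    seqs <- do.call(rbind, strsplit(toupper(aa), ""))
  }
  rownames(seqs) <- NULL
  seqs[seqs == "."] <- "-"
  new("MsaAlignment", ids = ids, seqs = seqs)
}

#' Map reference residue numbers to alignment columns
#'
#' Ungapped positions of the reference sequence are counted from 1 and
#' mapped to the alignment columns that hold them.
#'
#' @param alignment an [MsaAlignment-class].
#' @param referenceId id of the reference sequence (e.g. `"TurB"`).
#' @return an [AlignmentColumnMap-class].
#' @export
mapReference <- function(alignment, referenceId) {
  i <- match(referenceId, alignment@ids)
  if (is.na(i))
    stop("lookup error: reference id '", referenceId, "' not in alignment")
  row <- alignment@seqs[i, ]
  cols <- which(row != "-")
  if (!length(cols)) stop("reference sequence is all gaps")
  new("AlignmentColumnMap", referenceId = referenceId,
      columnOfResidue = setNames(as.integer(cols), seq_along(cols)),
      alignment = alignment)
}

#' Conservation status of reference residues across homologs
#'
#' For each requested reference residue and each homolog: `identical` when
#' the homolog carries the same amino acid in the aligned column, `similar`
#' when it belongs to the same similarity group, `gap` for an alignment
#' gap, else `different`.  Alignment-column equivalence (not position-number
#' identity) defines correspondence.
#'
#' @param map an [AlignmentColumnMap-class].
#' @param residues reference residue numbers (ungapped positions).
#' @param similarityGroups partition of the amino-acid alphabet; default
#'   [defaultSimilarityGroups()].
#' @return data.frame with columns `residue`, `refAA`, `homolog`, `status`.
#' @export
conservationReport <- function(map, residues,
                               similarityGroups = defaultSimilarityGroups()) {
  residues <- as.integer(residues)
  known <- as.integer(names(map@columnOfResidue))
  if (any(!residues %in% known))
    stop("residues outside the reference range: ",
         paste(setdiff(residues, known), collapse = ", "))
  groupOf <- character()
  for (g in names(similarityGroups))
    groupOf[similarityGroups[[g]]] <- g
  aln <- map@alignment
  refRow <- match(map@referenceId, aln@ids)
  homologs <- aln@ids[-refRow]
  out <- do.call(rbind, lapply(residues, function(r) {
    col <- map@columnOfResidue[[as.character(r)]]
    refAA <- aln@seqs[refRow, col]
    status <- vapply(homologs, function(h) {
      aa <- aln@seqs[match(h, aln@ids), col]
      if (aa == "-") "gap"
      else if (aa == refAA) "identical"
      else if (!is.na(groupOf[aa]) && !is.na(groupOf[refAA]) &&
               groupOf[aa] == groupOf[refAA]) "similar"
      else "different"
    }, character(1))
    data.frame(residue = r, refAA = refAA, homolog = homologs,
               status = unname(status), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a conservation report as TSV
#'
#' @param report data.frame from [conservationReport()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeConservationReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
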