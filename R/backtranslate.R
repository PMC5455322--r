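#' Back-translate a protein alignment onto coding sequences
#'
#' Expands each aligned amino-acid row to codons using the gene's CDS:
#' every residue becomes its next codon, every gap becomes `---`, so gap
#' columns stay in whole-codon units.  Each CDS must translate (standard
#' code; one trailing stop codon tolerated and dropped) to its ungapped
#' protein row.
#'
#' @param protein_alignment Named character vector of equal-length
#'   aligned amino-acid strings (gaps as `-`).
#' @param cds_by_id Named character vector of coding sequences covering
#'   every alignment row.
#' @return Named character vector of codon-aligned nucleotide strings;
#'   stripping gaps recovers the input CDS (minus a trailing stop).
#' @export
backtranslate <- function(protein_alignment, cds_by_id) {
  ids <- names(protein_alignment)
  if (is.null(ids) || anyNA(ids))
    stop("protein alignment rows must be named")
  widths <- nchar(protein_alignment)
  if (length(unique(widths)) > 1L)
    stop("alignment rows differ in length")
  missing <- setdiff(ids, names(cds_by_id))
  if (length(missing) > 0L)
    stop("no CDS for: ", paste(missing, collapse = ", "))
  out <- character(length(ids))
  names(out) <- ids
  for (id in ids) {
    cds <- toupper(cds_by_id[[id]])
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length of ", id, " (", nchar(cds), ") not divisible by 3")
    prot <- translate_cds(cds)
    # tolerate (and drop) a single trailing stop codon
    if (nchar(prot) > 1L && substring(prot, nchar(prot)) == "*") {
      prot <- substring(prot, 1L, nchar(prot) - 1L)
      cds <- substring(cds, 1L, nchar(cds) - 3L)
    }
    row <- strsplit(toupper(protein_alignment[[id]]), "")[[1L]]
    ungapped <- row[row != "-"]
    trans <- strsplit(prot, "")[[1L]]
    if (length(trans) != length(ungapped))
      stop("CDS of ", id, " translates to ", length(trans),
           " residues but alignment row has ", length(ungapped))
    mism <- which(trans != ungapped)
    if (length(mism) > 0L)
      stop("translation mismatch for ", id, " at residue ", mism[1L],
           ": CDS gives '", trans[mism[1L]], "', alignment has '",
           ungapped[mism[1L]], "'")
    cods <- split_codons(cds)
    expanded <- character(length(row))
    expanded[row == "-"] <- "---"
    expanded[row != "-"] <- cods
    out[[id]] <- paste(expanded, collapse = "")
  }
  out
}
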