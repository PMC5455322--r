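## Gene models are rows of a plain data.frame (one row per gene) with a
## list column of exon coordinate matrices.  All coordinates are 1-based
## inclusive (GFF3 convention) and no operation reinterprets them.

#' Construct a table of gene models
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param species Species tag (recycled).
#' @param seqid Chromosome or scaffold name.
#' @param start,end 1-based inclusive span of the gene.
#' @param strand `"+"` or `"-"`.
#' @param exons List of two-column matrices (`start`, `end`), one per
#'   gene, sorted ascending and non-overlapping, each within the gene
#'   span.  Defaults to one exon spanning the gene.
#' @return data.frame of class `gene_table` with columns `gene_id`,
#'   `species`, `seqid`, `start`, `end`, `strand` and list column
#'   `exons`.
#' @export
gene_table <- function(gene_id, species = NA_character_, seqid, start, end,
                       strand = "+", exons = NULL) {
  n <- length(gene_id)
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i)
      cbind(start = start[i], end = end[i]))
  df <- data.frame(
    gene_id = as.character(gene_id),
    species = rep_len(as.character(species), n),
    seqid = rep_len(as.character(seqid), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  df$exons <- exons
  class(df) <- c("gene_table", "data.frame")
  validate_gene_table(df)
}

#' Validate gene-model invariants
#'
#' Checks unique ids, `start <= end`, strand alphabet, and that exons
#' are sorted, non-overlapping and contained in the gene span.
#'
#' @param genes A `gene_table`.
#' @return The input, invisibly usable, after validation.
#' @export
validate_gene_table <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  bad <- which(genes$start > genes$end)
  if (length(bad) > 0L)
    stop("start > end for gene ", genes$gene_id[bad[1L]])
  if (!all(genes$strand %in% c("+", "-", "*", NA)))
    stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0L)
      stop("gene ", genes$gene_id[i], " has no exons")
    if (any(ex[, 1L] > ex[, 2L]))
      stop("exon with start > end in gene ", genes$gene_id[i])
    if (is.unsorted(ex[, 1L]))
      stop("exons not sorted ascending in gene ", genes$gene_id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      stop("overlapping exons in gene ", genes$gene_id[i])
    if (min(ex[, 1L]) < genes$start[i] || max(ex[, 2L]) > genes$end[i])
      stop("exon outside gene span in gene ", genes$gene_id[i])
  }
  genes
}

## Ordering key for chromosome/scaffold names: numbered chromosomes
## ("Chr1", "chr02", ...) in natural numeric order first, then all other
## seqids (scaffolds) lexicographically.
#' @noRd
seqid_rank <- function(seqid) {
  m <- regmatches(seqid, regexec("^[Cc]hr0*([0-9]+)[A-Za-z]?$", seqid))
  num <- vapply(m, function(x) if (length(x) == 2L)
    as.numeric(x[2L]) else NA_real_, numeric(1))
  # secondary letter (e.g. the duplicated copy "chr1b") sorts after the base
  suffix <- ifelse(is.na(num), seqid,
                   sub("^[Cc]hr0*[0-9]+", "", seqid))
  list(is_scaffold = is.na(num),
       number = ifelse(is.na(num), Inf, num),
       tiebreak = suffix)
}

#' Order gene models by genomic position
#'
#' Numbered chromosomes first in natural numeric order, scaffolds after
#' them lexicographically, then ascending start; residual ties broken by
#' `gene_id`.
#'
#' @param genes A `gene_table` (or data.frame with `seqid`, `start`,
#'   `gene_id`).
#' @return Integer permutation ordering the rows.
#' @export
genomic_order <- function(genes) {
  key <- seqid_rank(genes$seqid)
  order(key$is_scaffold, key$number, key$tiebreak, genes$seqid,
        genes$start, genes$gene_id)
}
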