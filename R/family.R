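## Family membership from domain-search hits, positional naming, and
## gene-structure summaries.

#' Filter domain hits to define family membership
#'
#' A gene is retained iff it has at least one hit to the family domain
#' with E-value strictly below the threshold (only domain-containing
#' sequences are kept).  When `domain_length` is supplied, a hit must
#' additionally cover at least `min_coverage` of that length, a proxy
#' for the usual web-tool domain validation step.
#'
#' @param hits data.frame of domain hits (see [read_domain_hits()]).
#' @param domain_acc Accession of the family domain (e.g. `"PF04873"`);
#'   `NULL` accepts hits to any accession.
#' @param threshold E-value cutoff, strict `<` (default 0.001).
#' @param domain_length,min_coverage Optional coverage requirement.
#' @return Character vector of retained gene ids (sorted, unique).
#' @export
filter_domain_hits <- function(hits, domain_acc = NULL, threshold = 0.001,
                               domain_length = NULL, min_coverage = 0.5) {
  if (nrow(hits) == 0L) {
    warning("empty domain-hit table: no family members")
    return(character(0))
  }
  keep <- hits$evalue < threshold
  if (!is.null(domain_acc)) keep <- keep & hits$domain_acc == domain_acc
  if (!is.null(domain_length))
    keep <- keep &
      (hits$hit_end - hits$hit_start + 1L) >= min_coverage * domain_length
  sort(unique(hits$gene_id[keep]))
}

#' Assign positional names to family members
#'
#' Orders members by chromosome (natural numeric order, scaffolds after
#' all chromosomes, lexicographically among themselves) and ascending
#' start, then names them `<prefix><tag><rank>` from rank 1 — the
#' naming scheme behind e.g. `PbEIL1..PbEIL10`.  Ties in (seqid, start)
#' are broken deterministically by gene id and reported.
#'
#' @param genes `gene_table` rows for the family members of one species.
#' @param species_prefix Species prefix (e.g. `"Pb"`).
#' @param family_tag Family tag (e.g. `"EIL"`).
#' @return data.frame with `assigned_name`, `gene_id`, `seqid`, `start`,
#'   `end`, `strand`, `n_introns`, in naming order.
#' @export
assign_family_names <- function(genes, species_prefix, family_tag) {
  if (nrow(genes) == 0L)
    return(data.frame(assigned_name = character(), gene_id = character(),
                      seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_introns = integer(), stringsAsFactors = FALSE))
  dup <- duplicated(paste(genes$seqid, genes$start, sep = "\r")) |
    duplicated(paste(genes$seqid, genes$start, sep = "\r"),
               fromLast = TRUE)
  if (any(dup))
    message("tie on (seqid, start) for: ",
            paste(genes$gene_id[dup], collapse = ", "),
            "; broken by gene_id")
  ord <- genomic_order(genes)
  out <- data.frame(
    assigned_name = paste0(species_prefix, family_tag,
                           seq_along(ord)),
    gene_id = genes$gene_id[ord],
    seqid = genes$seqid[ord],
    start = genes$start[ord],
    end = genes$end[ord],
    strand = genes$strand[ord],
    n_introns = vapply(genes$exons[ord], nrow, integer(1)) - 1L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Count family members per chromosome/scaffold
#'
#' @param genes `gene_table` (or any data.frame with `seqid`).
#' @return Named integer vector of counts, in genomic seqid order;
#'   counts sum to the family size.
#' @export
chromosome_distribution <- function(genes) {
  if (nrow(genes) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(genes$seqid)
  uniq <- names(tab)
  key <- seqid_rank(uniq)
  ord <- order(key$is_scaffold, key$number, key$tiebreak, uniq)
  setNames(as.integer(tab[uniq[ord]]), uniq[ord])
}

#' Intron count of a gene model
#'
#' @param gene One row of a `gene_table`.
#' @return Number of introns, i.e. exons minus one.
#' @export
intron_count <- function(gene) {
  ex <- gene$exons[[1L]]
  if (is.null(ex) || nrow(ex) == 0L)
    stop("gene ", gene$gene_id, " has no exons")
  nrow(ex) - 1L
}

#' Signed exon-number difference between two gene models
#'
#' Used to flag paralog pairs whose exon-intron organization diverged
#' (single intron gain/loss events).
#'
#' @param a,b Single rows of a `gene_table`.
#' @return `n_exons(a) - n_exons(b)`.
#' @export
compare_pair_structure <- function(a, b) {
  nrow(a$exons[[1L]]) - nrow(b$exons[[1L]])
}
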