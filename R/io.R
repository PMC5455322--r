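## Readers and writers for the standard formats the pipeline touches:
## GFF3 gene models, FASTA sequences, and the tabular homolog-pair,
## domain-hit and Ct inputs.

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon` features into a [gene_table()].  Exons
#' are attached to their gene through the `Parent` attribute (directly
#' or via an mRNA); genes without exon features get a single exon
#' spanning the gene.  Coordinates are kept 1-based inclusive.
#'
#' @param path GFF3 file.
#' @param species Optional species tag stored on every gene.  The
#'   default `NULL` recovers per-gene species from the GFF source
#'   column when present (as written by [write_gff3()]), else `NA`.
#' @return A `gene_table`.
#' @export
read_gff3 <- function(path, species = NULL) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfields < 9L)) {
    bad <- which(body)[which(nfields < 9L)[1L]]
    stop("malformed GFF3 line ", bad, " in ", path,
         ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  first_parent <- function(p) vapply(p, function(x)
    if (length(x) == 0L) NA_character_ else as.character(x[[1L]]),
    character(1))
  parent <- if ("Parent" %in% names(df)) first_parent(df$Parent)
            else rep(NA_character_, nrow(df))
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  mrna_gene <- parent[df$type == "mRNA"]
  names(mrna_gene) <- mrna$ID
  ex <- df[df$type == "exon", , drop = FALSE]
  ex_parent <- parent[df$type == "exon"]
  ex_gene <- ifelse(ex_parent %in% genes$ID, ex_parent,
                    unname(mrna_gene[ex_parent]))
  exon_list <- lapply(genes$ID, function(g) {
    rows <- which(ex_gene == g)
    if (length(rows) == 0L)
      return(cbind(start = genes$start[genes$ID == g],
                   end = genes$end[genes$ID == g]))
    m <- cbind(start = ex$start[rows], end = ex$end[rows])
    m[order(m[, 1L]), , drop = FALSE]
  })
  if (is.null(species)) {
    src <- if ("source" %in% names(genes)) as.character(genes$source)
           else rep(NA_character_, nrow(genes))
    species <- ifelse(is.na(src) | src %in% c(".", "famsynt"),
                      NA_character_, src)
  }
  gene_table(
    gene_id = genes$ID, species = species, seqid = genes$seqnames,
    start = genes$start, end = genes$end,
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "+"),
    exons = exon_list
  )
}

#' Write gene models to a GFF3 file
#'
#' Emits `gene`, `mRNA` and `exon` features, recording each gene's
#' species (when known) in the source column; [read_gff3()] on the
#' output reproduces the input table.
#'
#' @param genes A `gene_table`.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  validate_gene_table(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    src <- if (is.na(g$species)) "famsynt" else g$species
    line <- function(type, s, e, attrs)
      paste(g$seqid, src, type, s, e, ".", g$strand, ".", attrs,
            sep = "\t")
    writeLines(line("gene", g$start, g$end,
                    paste0("ID=", g$gene_id)), con)
    mid <- paste0(g$gene_id, ".t1")
    writeLines(line("mRNA", g$start, g$end,
                    paste0("ID=", mid, ";Parent=", g$gene_id)), con)
    ex <- genes$exons[[i]]
    for (k in seq_len(nrow(ex)))
      writeLines(line("exon", ex[k, 1L], ex[k, 2L],
                      paste0("ID=", mid, ".exon", k, ";Parent=", mid)),
                 con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of uppercased sequences; empty file
#'   gives an empty vector.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a homolog-pair table
#'
#' Accepts a BLAST outfmt-6-like TSV (qseqid, sseqid, ..., evalue,
#' bitscore; no header) or a headered TSV with columns `gene_a`,
#' `gene_b`, `score`, `evalue`.  Self-hits are dropped; reciprocal
#' duplicates are collapsed to one canonical pair (lexicographic id
#' order) keeping the lowest E-value and the highest score.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`,
#'   `evalue`.
#' @export
read_homolog_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_a", first, fixed = TRUE)
  if (has_header) {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 12L)
      stop("homolog table must have 12 outfmt-6 columns or a ",
           "gene_a/gene_b/score/evalue header")
    raw <- data.frame(gene_a = as.character(raw[[1L]]),
                      gene_b = as.character(raw[[2L]]),
                      score = raw[[12L]], evalue = raw[[11L]],
                      stringsAsFactors = FALSE)
  }
  if (!is.numeric(raw$evalue))
    stop("non-numeric evalue column in ", path)
  if (any(raw$evalue < 0)) stop("negative evalue in ", path)
  canonicalize_pairs(raw)
}

#' @noRd
canonicalize_pairs <- function(df) {
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  df$gene_a <- a
  df$gene_b <- b
  df <- df[order(a, b, df$evalue, -df$score), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_a, df$gene_b, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[, c("gene_a", "gene_b", "score", "evalue")]
}

#' Read a tabular domain-hit file
#'
#' Headered TSV with columns `gene_id`, `domain_acc`, `evalue`,
#' `hit_start`, `hit_end` (HMMER tblout-like content).
#'
#' @param path TSV file.
#' @return data.frame of domain hits.
#' @export
read_domain_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain_acc", "evalue", "hit_start", "hit_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("domain-hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$evalue) || any(df$evalue < 0))
    stop("evalue must be numeric and non-negative")
  if (any(df$hit_start > df$hit_end))
    stop("hit_start > hit_end in domain-hit table")
  df
}

#' Read a qRT-PCR Ct table
#'
#' Headered TSV with columns `gene_id`, `sample`, `replicate`, `ct`.
#'
#' @param path TSV file.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "sample", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$ct) || any(df$ct <= 0))
    stop("ct must be numeric and positive")
  df
}
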