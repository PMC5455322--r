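## Nei-Gojobori (1986) Ka/Ks estimation, sliding-window selection scans,
## selection-regime classification, flanking-Ks averaging and Ks-epoch
## dating of duplication events.

#' Nei-Gojobori (1986) Ka/Ks for a pair of aligned coding sequences
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon from the
#' standard genetic code (changes to stop codons count as nonsynonymous),
#' averages site counts over the two sequences, resolves codons differing
#' at several positions by equal-weight averaging over all substitution
#' pathways that avoid stop codons, and applies the Jukes-Cantor
#' multiple-hit correction to the proportions `pS = sd/S`, `pN = nd/N`.
#'
#' Codon columns containing a gap or ambiguity character, a stop codon,
#' or whose every substitution pathway passes through a stop codon are
#' excluded for the pair (pairwise deletion at codon granularity).
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length
#'   divisible by 3 (gaps as `-`).
#' @return Object of class `kaks`: list with `ka`, `ks`, `ratio`, `S`,
#'   `N`, `sd`, `nd`, `n_codons` (comparable codons), `saturated_s`,
#'   `saturated_n`.  `ratio` is `NA` when `Ks` is 0, undefined or
#'   saturated.
#' @examples
#' r <- ng86(strrep("AAA", 12), paste0(strrep("AAA", 11), "AAG"))
#' r$ks  # 0.304099
#' @export
ng86 <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  if (nchar(seq_a) %% 3L != 0L)
    stop("aligned length (", nchar(seq_a), ") is not divisible by 3")
  u <- codon_universe()
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  ia <- match(ca, u$codons)
  ib <- match(cb, u$codons)
  usable <- !is.na(ia) & !is.na(ib) & !u$is_stop[pmax(ia, 1L)] &
    !u$is_stop[pmax(ib, 1L)]
  usable[is.na(usable)] <- FALSE
  tabs <- pathway_tables()
  sdv <- rep(NA_real_, length(ca))
  sdv[usable] <- tabs$sd[cbind(ia[usable], ib[usable])]
  blocked <- usable & is.na(sdv)
  if (any(blocked))
    warning(sum(blocked), " codon pair(s) skipped: all substitution ",
            "pathways pass through stop codons")
  usable <- usable & !is.na(sdv)
  n_cod <- sum(usable)
  if (n_cod == 0L)
    stop("no comparable codon pairs in the alignment")
  syn <- syn_site_table()
  S <- (sum(syn[ia[usable]]) + sum(syn[ib[usable]])) / 2
  N <- 3 * n_cod - S
  sd_ <- sum(tabs$sd[cbind(ia[usable], ib[usable])])
  nd_ <- sum(tabs$nd[cbind(ia[usable], ib[usable])])
  pS <- if (S > 0) sd_ / S else NA_real_
  pN <- if (N > 0) nd_ / N else NA_real_
  sat_s <- !is.na(pS) && pS >= 0.75
  sat_n <- !is.na(pN) && pN >= 0.75
  ks <- if (is.na(pS) || sat_s) NA_real_ else jc_correct(pS)
  ka <- if (is.na(pN) || sat_n) NA_real_ else jc_correct(pN)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(
    list(ka = ka, ks = ks, ratio = ratio, S = S, N = N, sd = sd_,
         nd = nd_, n_codons = n_cod, saturated_s = sat_s,
         saturated_n = sat_n),
    class = "kaks"
  )
}

#' @export
print.kaks <- function(x, ...) {
  cat("Nei-Gojobori (1986) estimate over", x$n_codons, "codons\n")
  cat(sprintf("  Ka = %s  Ks = %s  Ka/Ks = %s\n",
              format(x$ka, digits = 6), format(x$ks, digits = 6),
              format(x$ratio, digits = 6)))
  cat(sprintf("  S = %.3f  N = %.3f  sd = %.3f  nd = %.3f\n",
              x$S, x$N, x$sd, x$nd))
  if (x$saturated_s) cat("  synonymous differences saturated\n")
  if (x$saturated_n) cat("  nonsynonymous differences saturated\n")
  invisible(x)
}

#' Number of sliding windows over an aligned length
#'
#' @param aligned_length Alignment length in nucleotides.
#' @param window,step Window and step sizes in nucleotides.
#' @return `floor((aligned_length - window)/step) + 1`, or 0 when the
#'   alignment is shorter than one window.
#' @export
n_windows <- function(aligned_length, window = 150L, step = 9L) {
  ifelse(aligned_length < window, 0L,
         (aligned_length - window) %/% step + 1L)
}

#' Sliding-window Ka/Ks scan of a codon alignment
#'
#' Applies [ng86()] to successive windows of the alignment (default 150
#' nt = 50 codons, step 9 nt = 3 codons, so windows stay on codon
#' boundaries).  Window positions are alignment coordinates: gaps count
#' toward positioning but are excluded from estimation.  Windows with
#' fewer than `min_codons` comparable codons are reported with `NA`
#' estimates; a trailing partial window is dropped.
#'
#' @param seq_a,seq_b Aligned coding sequences as for [ng86()].
#' @param window,step Window/step in nucleotides (multiples of 3).
#' @param min_codons Minimum comparable codons for a window to be
#'   estimated (default 10).
#' @return data.frame with columns `start`, `end` (1-based alignment
#'   coordinates), `ka`, `ks`, `ratio`, `n_codons`.
#' @export
sliding_window <- function(seq_a, seq_b, window = 150L, step = 9L,
                           min_codons = 10L) {
  stopifnot(window %% 3L == 0L, step %% 3L == 0L)
  L <- nchar(seq_a)
  if (nchar(seq_b) != L) stop("aligned sequences differ in length")
  nw <- n_windows(L, window, step)
  if (nw == 0L) {
    warning("aligned length ", L, " shorter than one window (", window, ")")
    return(data.frame(start = integer(), end = integer(),
                      ka = numeric(), ks = numeric(), ratio = numeric(),
                      n_codons = integer()))
  }
  starts <- 1L + step * (seq_len(nw) - 1L)
  out <- data.frame(start = starts, end = starts + window - 1L,
                    ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                    n_codons = 0L)
  for (w in seq_len(nw)) {
    wa <- substr(seq_a, out$start[w], out$end[w])
    wb <- substr(seq_b, out$start[w], out$end[w])
    res <- tryCatch(suppressWarnings(ng86(wa, wb)), error = function(e) NULL)
    if (is.null(res)) next
    out$n_codons[w] <- res$n_codons
    if (res$n_codons >= min_codons) {
      out$ka[w] <- res$ka
      out$ks[w] <- res$ks
      out$ratio[w] <- res$ratio
    }
  }
  out
}

#' Classify a Ka/Ks ratio into a selection regime
#'
#' Ka/Ks > 1 indicates positive selection, < 1 purifying (negative)
#' selection, and = 1 (within tolerance) neutral drift.
#'
#' @param ratio Ka/Ks value(s); `NA` allowed.
#' @param tol Tolerance for equality with 1.
#' @return Character vector in
#'   `{"positive","purifying","neutral","undefined"}`.
#' @export
classify_selection <- function(ratio, tol = 1e-9) {
  out <- rep("undefined", length(ratio))
  def <- !is.na(ratio)
  out[def & abs(ratio - 1) <= tol] <- "neutral"
  out[def & ratio > 1 + tol] <- "positive"
  out[def & ratio < 1 - tol] <- "purifying"
  out
}

#' Mean synonymous distance of a block's flanking gene pairs
#'
#' Averages defined, non-saturated Ks over the matched non-anchor pairs
#' of a syntenic block, the quantity used to date the duplication or
#' speciation event behind the block.  Pairs whose coding sequences
#' cannot be compared (missing CDS, unequal lengths) are skipped with a
#' warning.
#'
#' @param block A `syntenic_block` from [call_block()].
#' @param cds_by_id Named character vector of coding sequences.
#' @return List with `mean_ks` (`NA` if no usable pair), `n_pairs`
#'   (contributing pairs) and `ks` (per-pair values).
#' @export
mean_flanking_ks <- function(block, cds_by_id) {
  stopifnot(inherits(block, "syntenic_block"))
  pairs <- block$matched_pairs
  anchors <- c(block$region_a$anchor, block$region_b$anchor)
  keep <- !(pairs$gene_a %in% anchors | pairs$gene_b %in% anchors)
  pairs <- pairs[keep, , drop = FALSE]
  ks <- numeric(0)
  skipped <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- cds_by_id[[pairs$gene_a[k]]]
    b <- cds_by_id[[pairs$gene_b[k]]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b) ||
        nchar(a) != nchar(b)) {
      skipped <- skipped + 1L
      next
    }
    res <- tryCatch(suppressWarnings(ng86(a, b)), error = function(e) NULL)
    if (is.null(res) || is.na(res$ks) || res$saturated_s) next
    ks <- c(ks, res$ks)
  }
  if (skipped > 0L)
    warning(skipped, " flanking pair(s) skipped (missing or ",
            "length-mismatched CDS)")
  if (length(ks) == 0L) {
    warning("no usable flanking pairs; mean Ks undefined")
    return(list(mean_ks = NA_real_, n_pairs = 0L, ks = ks))
  }
  list(mean_ks = mean(ks), n_pairs = length(ks), ks = ks)
}

#' Date a duplication event from the mean flanking Ks
#'
#' Maps a mean synonymous distance onto the whole-genome-duplication
#' epochs reported for pear: the recent WGD (30-45 MYA, Ks ~ 0.15-0.3)
#' and the ancient WGD shared across Rosaceae (~140 MYA, Ks ~ 1.5-1.8).
#' Both intervals are closed; values outside both are left unassigned.
#'
#' @param mean_ks Mean Ks value(s).
#' @param recent,ancient Length-2 numeric Ks intervals.
#' @return Character vector in
#'   `{"recent_WGD","ancient_WGD","unassigned"}` (`NA` input ->
#'   `"unassigned"`).
#' @export
date_duplication <- function(mean_ks, recent = c(0.15, 0.3),
                             ancient = c(1.5, 1.8)) {
  out <- rep("unassigned", length(mean_ks))
  def <- !is.na(mean_ks)
  out[def & mean_ks >= recent[1] & mean_ks <= recent[2]] <- "recent_WGD"
  out[def & mean_ks >= ancient[1] & mean_ks <= ancient[2]] <- "ancient_WGD"
  out
}
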