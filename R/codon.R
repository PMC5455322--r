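## Genetic-code tables shared by the Ka/Ks estimator and the sequence
## simulator.  All tables are derived from the standard code
## (Biostrings::GENETIC_CODE) and cached in the package environment on
## first use, so nothing binary is shipped.

.famsynt_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

#' @noRd
codon_universe <- function() {
  if (is.null(.famsynt_cache$codons)) {
    cods <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
    cods <- sort(cods)
    aa <- unname(Biostrings::GENETIC_CODE[cods])
    .famsynt_cache$codons <- cods
    .famsynt_cache$aa <- aa
    .famsynt_cache$is_stop <- aa == "*"
  }
  list(
    codons = .famsynt_cache$codons,
    aa = .famsynt_cache$aa,
    is_stop = .famsynt_cache$is_stop
  )
}

#' Translate a coding sequence under the standard genetic code
#'
#' @param cds Nucleotide string, length divisible by 3, `ACGT` alphabet.
#' @return Amino-acid string; stop codons translate to `"*"`.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length (", nchar(cds), ") is not divisible by 3")
  if (nchar(cds) == 0L) return("")
  cods <- split_codons(cds)
  u <- codon_universe()
  idx <- match(cods, u$codons)
  if (anyNA(idx))
    stop("non-ACGT codon(s): ", paste(unique(cods[is.na(idx)]), collapse = ", "))
  paste(u$aa[idx], collapse = "")
}

#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## Fraction of synonymous sites per codon (Nei-Gojobori counting): at each
## of the 3 positions, the fraction of the 3 possible changes that are
## synonymous; changes to stop codons count as nonsynonymous.
#' @noRd
syn_site_table <- function() {
  if (!is.null(.famsynt_cache$syn_sites)) return(.famsynt_cache$syn_sites)
  u <- codon_universe()
  s <- numeric(64L)
  names(s) <- u$codons
  for (i in seq_len(64L)) {
    if (u$is_stop[i]) { s[i] <- NA_real_; next }
    cod <- strsplit(u$codons[i], "")[[1L]]
    frac <- 0
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, cod[pos])) {
        alt <- cod
        alt[pos] <- nt
        j <- match(paste(alt, collapse = ""), u$codons)
        if (!u$is_stop[j] && u$aa[j] == u$aa[i]) frac <- frac + 1 / 3
      }
    }
    s[i] <- frac
  }
  .famsynt_cache$syn_sites <- s
  s
}

## Pathway-averaged synonymous/nonsynonymous difference counts for every
## ordered pair of sense codons.  Codons differing at k positions are
## resolved by enumerating all k! substitution orders; pathways passing
## through a stop codon are discarded; counts are averaged with equal
## weight over the surviving pathways.  Pairs whose every pathway is
## blocked get NA and are skipped (and reported) by ng86().
#' @noRd
pathway_tables <- function() {
  if (!is.null(.famsynt_cache$sd_tab)) {
    return(list(sd = .famsynt_cache$sd_tab, nd = .famsynt_cache$nd_tab))
  }
  u <- codon_universe()
  perms <- list(
    `1` = list(1L),
    `2` = list(1:2, 2:1),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  sd_tab <- matrix(0, 64L, 64L, dimnames = list(u$codons, u$codons))
  nd_tab <- sd_tab
  chars <- strsplit(u$codons, "")
  for (i in seq_len(64L)) {
    if (u$is_stop[i]) { sd_tab[i, ] <- NA; nd_tab[i, ] <- NA; next }
    for (j in seq_len(64L)) {
      if (u$is_stop[j]) { sd_tab[i, j] <- NA; nd_tab[i, j] <- NA; next }
      if (i == j) next
      diffpos <- which(chars[[i]] != chars[[j]])
      k <- length(diffpos)
      tot_s <- 0; tot_n <- 0; n_ok <- 0L
      for (ord in perms[[k]]) {
        cur <- chars[[i]]
        s <- 0L; n <- 0L
        ok <- TRUE
        for (p in diffpos[ord]) {
          nxt <- cur
          nxt[p] <- chars[[j]][p]
          a <- match(paste(cur, collapse = ""), u$codons)
          b <- match(paste(nxt, collapse = ""), u$codons)
          if (u$is_stop[b]) { ok <- FALSE; break }
          if (u$aa[a] == u$aa[b]) s <- s + 1L else n <- n + 1L
          cur <- nxt
        }
        if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1L }
      }
      if (n_ok == 0L) {
        sd_tab[i, j] <- NA; nd_tab[i, j] <- NA
      } else {
        sd_tab[i, j] <- tot_s / n_ok
        nd_tab[i, j] <- tot_n / n_ok
      }
    }
  }
  .famsynt_cache$sd_tab <- sd_tab
  .famsynt_cache$nd_tab <- nd_tab
  list(sd = sd_tab, nd = nd_tab)
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' @param p Proportion of observed differences per site.
#' @return Corrected distance `-(3/4) log(1 - 4p/3)`; `NA` when
#'   `p >= 3/4` (saturation).
#' @export
jc_correct <- function(p) {
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3) + 0  # +0 normalizes -0
  d
}
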