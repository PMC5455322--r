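# Independent oracles, written without reference to the package
# internals: a brute-force pathway-enumeration Ka/Ks calculator and a
# brute-force maximum bipartite matcher.

oracle_code <- Biostrings::GENETIC_CODE

oracle_neighbors <- function(codon) {
  out <- character(0)
  for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (substr(codon, pos, pos) == nt) next
    alt <- codon
    substr(alt, pos, pos) <- nt
    out <- c(out, alt)
  }
  out
}

oracle_syn_fraction <- function(codon) {
  frac <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == nt) next
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (oracle_code[[alt]] != "*" &&
          oracle_code[[alt]] == oracle_code[[codon]])
        frac <- frac + 1 / 3
    }
  }
  frac
}

# enumerate all substitution orders recursively
oracle_orders <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_orders(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

# pathway-averaged (syn, nonsyn) difference counts for one codon pair;
# NULL when every pathway passes through a stop codon
oracle_pair_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(0, 0))
  acc <- c(0, 0)
  n_ok <- 0L
  for (ord in oracle_orders(pos)) {
    cur <- c1
    steps <- c(0, 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code[[nxt]] == "*") { ok <- FALSE; break }
      if (oracle_code[[cur]] == oracle_code[[nxt]])
        steps[1] <- steps[1] + 1
      else steps[2] <- steps[2] + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + steps; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(NULL)
  acc / n_ok
}

oracle_ng86 <- function(seq_a, seq_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3),
                                  seq(3, nchar(s), 3))
  ca <- split3(toupper(seq_a))
  cb <- split3(toupper(seq_b))
  S <- N <- sdiff <- ndiff <- 0
  n_used <- 0L
  for (k in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[k]) || grepl("[^ACGT]", cb[k])) next
    if (oracle_code[[ca[k]]] == "*" || oracle_code[[cb[k]]] == "*") next
    counts <- oracle_pair_counts(ca[k], cb[k])
    if (is.null(counts)) next
    n_used <- n_used + 1L
    S <- S + (oracle_syn_fraction(ca[k]) + oracle_syn_fraction(cb[k])) / 2
    sdiff <- sdiff + counts[1]
    ndiff <- ndiff + counts[2]
  }
  N <- 3 * n_used - S
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_
    else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) sdiff / S else NA_real_
  pN <- if (N > 0) ndiff / N else NA_real_
  list(S = S, N = N, sd = sdiff, nd = ndiff, n_codons = n_used,
       ks = jc(pS), ka = jc(pN))
}

# random pair of aligned sense-codon sequences with point differences
random_codon_fixture <- function(n_codons = 8L, n_mut = 3L) {
  sense <- names(oracle_code)[oracle_code != "*"]
  a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  b <- a
  for (m in seq_len(n_mut)) {
    repeat {
      p <- sample(nchar(b), 1L)
      cand <- b
      substr(cand, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(b, p, p)), 1L)
      cs <- p - (p - 1L) %% 3L
      if (oracle_code[[substr(cand, cs, cs + 2L)]] != "*") {
        b <- cand
        break
      }
    }
  }
  list(a = a, b = b)
}

# brute-force maximum 1-to-1 matching size over listed homolog pairs
oracle_max_matching <- function(pairs_a, pairs_b) {
  n <- length(pairs_a)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    genes <- c(pairs_a[sel], pairs_b[sel])
    if (anyDuplicated(genes)) next
    best <- max(best, length(sel))
  }
  best
}
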