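## Genome-evolution simulator: multi-species gene complements descended
## from a common ancestor through whole-genome duplication, tandem
## duplication, gene loss and local inversion, with coding sequences
## diverged under a specified dN/dS.  Every emitted object carries
## ground truth, so downstream stages are testable without external
## data.

#' Specification for a simulated gene-family data set
#'
#' Defaults describe the study system the package targets: four related
#' species, a recent whole-genome duplication in the first species only
#' (pear-like), a small family with one anchor per proto-chromosome,
#' purifying selection (omega = 0.2) at low divergence, and intergenic
#' spacing that puts roughly 6-9 genes in each 100-kb flank.
#'
#' @param n_species Number of species.
#' @param species Species tags.
#' @param n_ancestral_genes Ancestral gene count (>= 10).
#' @param n_chromosomes Ancestral proto-chromosomes.
#' @param wgd_species Species carrying a recent whole-genome
#'   duplication (each chromosome duplicated onto a new one, order
#'   preserved).
#' @param tandem_rate Per-copy probability of a tandem duplicate.
#' @param loss_rate Per-copy probability of loss.
#' @param inversion_rate Per family-anchor flanking window, probability
#'   that the window's gene order is inverted.
#' @param intergenic_mean Mean intergenic distance (bp).
#' @param window_bp Flanking-window size used for inversion events.
#' @param n_decoys Random non-homologous homolog-table entries.
#' @param omega Nonsynonymous/synonymous rate ratio on every branch.
#' @param branch_subs Expected accepted substitutions per codon per
#'   branch.
#' @param kappa Transition/transversion proposal ratio.
#' @param seed Random seed.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_species = 4L, species = paste0("S", seq_len(n_species)),
                     n_ancestral_genes = 60L, n_chromosomes = 3L,
                     wgd_species = species[1L], tandem_rate = 0.05,
                     loss_rate = 0.05, inversion_rate = 0.1,
                     intergenic_mean = 10000, window_bp = 100000L,
                     n_decoys = 0L, omega = 0.2, branch_subs = 0.1,
                     kappa = 1, seed = 1L) {
  rates <- c(tandem_rate = tandem_rate, loss_rate = loss_rate,
             inversion_rate = inversion_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]")
  if (omega < 0) stop("omega must be >= 0")
  if (n_ancestral_genes < 10L) stop("n_ancestral_genes must be >= 10")
  if (!all(wgd_species %in% species))
    stop("wgd_species must be a subset of species")
  structure(
    list(n_species = n_species, species = species,
         n_ancestral_genes = as.integer(n_ancestral_genes),
         n_chromosomes = as.integer(n_chromosomes),
         wgd_species = wgd_species, tandem_rate = tandem_rate,
         loss_rate = loss_rate, inversion_rate = inversion_rate,
         intergenic_mean = intergenic_mean,
         window_bp = as.integer(window_bp),
         n_decoys = as.integer(n_decoys), omega = omega,
         branch_subs = branch_subs, kappa = kappa,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Random sense coding sequence
#'
#' @param n_codons Number of codons.
#' @return Nucleotide string with no stop codons.
#' @export
random_cds <- function(n_codons) {
  u <- codon_universe()
  sense <- u$codons[!u$is_stop]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' @noRd
is_transition <- function(from, to) {
  (from %in% c("A", "G") & to %in% c("A", "G")) |
    (from %in% c("C", "T") & to %in% c("C", "T"))
}

#' Evolve a coding sequence along one branch
#'
#' Accept/reject codon evolution: the number of accepted substitutions
#' is drawn Poisson(`branch_subs` x codons); each is realized by
#' proposing a site uniformly and a replacement nucleotide with
#' transition bias `kappa`, rejecting proposals that create stop
#' codons, accepting synonymous proposals always and nonsynonymous ones
#' with probability `omega`.
#'
#' @param cds Ancestral coding sequence (no stop codons, length
#'   divisible by 3).
#' @param branch_subs Expected accepted substitutions per codon.
#' @param omega Relative acceptance rate of nonsynonymous proposals.
#' @param kappa Transition/transversion proposal ratio.
#' @return Descendant coding sequence.
#' @export
evolve_cds <- function(cds, branch_subs, omega, kappa = 1) {
  u <- codon_universe()
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  cods <- split_codons(cds)
  idx <- match(cods, u$codons)
  if (anyNA(idx)) stop("CDS contains non-ACGT characters")
  if (any(u$is_stop[idx])) stop("ancestral CDS contains a stop codon")
  nt <- strsplit(cds, "")[[1L]]
  L <- length(nt)
  n_cod <- L %/% 3L
  k_total <- stats::rpois(1L, branch_subs * n_cod)
  accepted <- 0L
  guard <- 0L
  max_tries <- 1000L * max(k_total, 1L)
  while (accepted < k_total && guard < max_tries) {
    guard <- guard + 1L
    site <- sample.int(L, 1L)
    cur <- nt[site]
    alts <- setdiff(NUCS, cur)
    w <- ifelse(is_transition(cur, alts), kappa, 1)
    nt_new <- sample(alts, 1L, prob = w)
    cs <- site - (site - 1L) %% 3L
    old_cod <- paste(nt[cs:(cs + 2L)], collapse = "")
    tmp <- nt[cs:(cs + 2L)]
    tmp[site - cs + 1L] <- nt_new
    new_cod <- paste(tmp, collapse = "")
    j <- match(new_cod, u$codons)
    if (u$is_stop[j]) next
    syn <- u$aa[match(old_cod, u$codons)] == u$aa[j]
    if (syn || stats::runif(1L) < omega) {
      nt[site] <- nt_new
      accepted <- accepted + 1L
    }
  }
  paste(nt, collapse = "")
}

#' Evolve two independent descendants of one coding sequence
#'
#' @param ancestral_cds Ancestral CDS (no stop codons).
#' @param branch_subs,omega,kappa As in [evolve_cds()]; applied per
#'   branch.
#' @param seed Optional seed for reproducibility.
#' @return List with elements `a` and `b`.
#' @export
evolve_codon_pair <- function(ancestral_cds, branch_subs, omega,
                              kappa = 1, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  list(a = evolve_cds(ancestral_cds, branch_subs, omega, kappa),
       b = evolve_cds(ancestral_cds, branch_subs, omega, kappa))
}

#' Simulate multi-species gene complements with known truth
#'
#' Applies, per species: whole-genome duplication (for species listed
#' in the spec), tandem duplication, gene loss, coordinate assignment
#' with exponential intergenic gaps, and inversion of family-anchor
#' flanking windows (gene order mirrored within the window footprint).
#' Coding sequences are evolved independently from each ancestral CDS.
#' Deterministic given the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return List of class `famsynt_sim` with elements `genes`
#'   (a `gene_table` over all species), `cds` and `proteins` (named
#'   vectors), `homologs` (pair table), `hits` (domain-hit table for
#'   family descendants plus decoy hits), and `truth` (ancestral table,
#'   copy table of surviving copies, `all_copies` including lost ones,
#'   ortholog map, event log, per-window inversion flags, family ids,
#'   true omega).
#' @export
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_ancestral_genes
  per_chr <- ceiling(n / spec$n_chromosomes)
  anc <- data.frame(
    anc_id = sprintf("ANC%03d", seq_len(n)),
    chrom = rep(seq_len(spec$n_chromosomes), each = per_chr)[seq_len(n)],
    stringsAsFactors = FALSE
  )
  anc$rank <- stats::ave(seq_len(n), anc$chrom, FUN = seq_along)
  n_codons <- sample(150:400, n, replace = TRUE)
  n_exons <- sample(1:9, n, replace = TRUE)
  anc_cds <- setNames(vapply(n_codons, random_cds, character(1)),
                      anc$anc_id)
  # one family anchor per proto-chromosome, at the middle rank
  family_anc <- vapply(split(anc$anc_id, anc$chrom), function(ids)
    ids[(length(ids) + 1L) %/% 2L], character(1))
  family_anc <- unname(family_anc)

  copy_rows <- list()
  all_copy_rows <- list()   # every copy ever created, including lost ones
  event_rows <- list()
  order_by_species <- list()   # species -> chrom -> ordered copy ids
  counter <- 0L
  new_event <- function(species, type, chrom, copy_id = NA,
                        parent = NA, from = NA, to = NA)
    data.frame(species = species, type = type, chrom = chrom,
               copy_id = copy_id, parent = parent,
               from = from, to = to, stringsAsFactors = FALSE)

  for (sp in spec$species) {
    chroms <- list()
    copy_anc <- character(0)    # copy id -> ancestral id
    copy_origin <- character(0)
    copy_chrom <- character(0)
    # primary copies in ancestral order
    for (ch in seq_len(spec$n_chromosomes)) {
      ids <- anc$anc_id[anc$chrom == ch]
      cids <- character(length(ids))
      for (k in seq_along(ids)) {
        counter <- counter + 1L
        cids[k] <- paste0(sp, "_g", sprintf("%04d", counter))
        copy_anc[cids[k]] <- ids[k]
        copy_origin[cids[k]] <- "primary"
        copy_chrom[cids[k]] <- paste0("chr", ch)
      }
      chroms[[paste0("chr", ch)]] <- cids
    }
    # whole-genome duplication: each chromosome copied, order preserved
    if (sp %in% spec$wgd_species) {
      for (ch in seq_len(spec$n_chromosomes)) {
        src <- paste0("chr", ch)
        dst <- paste0("chr", ch, "b")
        ids <- copy_anc[chroms[[src]]]
        cids <- character(length(ids))
        for (k in seq_along(ids)) {
          counter <- counter + 1L
          cids[k] <- paste0(sp, "_g", sprintf("%04d", counter))
          copy_anc[cids[k]] <- ids[[k]]
          copy_origin[cids[k]] <- "wgd"
          copy_chrom[cids[k]] <- dst
        }
        chroms[[dst]] <- cids
        event_rows[[length(event_rows) + 1L]] <-
          new_event(sp, "wgd", dst, parent = src)
      }
    }
    # tandem duplication: adjacent copy inserted after its parent
    for (ch in names(chroms)) {
      out <- character(0)
      for (cid in chroms[[ch]]) {
        out <- c(out, cid)
        if (stats::runif(1L) < spec$tandem_rate) {
          counter <- counter + 1L
          tid <- paste0(sp, "_g", sprintf("%04d", counter))
          copy_anc[tid] <- copy_anc[[cid]]
          copy_origin[tid] <- "tandem"
          copy_chrom[tid] <- ch
          out <- c(out, tid)
          event_rows[[length(event_rows) + 1L]] <-
            new_event(sp, "tandem", ch, copy_id = tid, parent = cid)
        }
      }
      chroms[[ch]] <- out
    }
    # loss
    for (ch in names(chroms)) {
      keep <- stats::runif(length(chroms[[ch]])) >= spec$loss_rate
      for (cid in chroms[[ch]][!keep])
        event_rows[[length(event_rows) + 1L]] <-
          new_event(sp, "loss", ch, copy_id = cid)
      chroms[[ch]] <- chroms[[ch]][keep]
    }
    if (sum(lengths(chroms)) < 3L)
      stop("species ", sp, " retains fewer than 3 genes; ",
           "lower loss_rate or raise n_ancestral_genes")
    order_by_species[[sp]] <- chroms
    all_copy_rows[[length(all_copy_rows) + 1L]] <- data.frame(
      copy_id = names(copy_anc), species = sp,
      anc_id = unname(copy_anc), chrom = unname(copy_chrom),
      origin = unname(copy_origin), stringsAsFactors = FALSE
    )
    for (ch in names(chroms)) {
      ids <- chroms[[ch]]
      if (length(ids) == 0L) next
      copy_rows[[length(copy_rows) + 1L]] <- data.frame(
        copy_id = ids, species = sp, anc_id = unname(copy_anc[ids]),
        chrom = ch, origin = unname(copy_origin[ids]),
        stringsAsFactors = FALSE
      )
    }
  }
  copy_table <- do.call(rbind, copy_rows)
  all_copies <- do.call(rbind, all_copy_rows)

  # coordinates, exon structures, strands
  coord <- list()
  for (sp in spec$species) {
    for (ch in names(order_by_species[[sp]])) {
      ids <- order_by_species[[sp]][[ch]]
      if (length(ids) == 0L) next
      pos <- 0L
      for (cid in ids) {
        aid <- copy_table$anc_id[copy_table$copy_id == cid]
        ai <- match(aid, anc$anc_id)
        cds_len <- 3L * n_codons[ai]
        nex <- n_exons[ai]
        ex_len <- rep(cds_len %/% nex, nex)
        ex_len[nex] <- ex_len[nex] + cds_len %% nex
        introns <- if (nex > 1L) sample(80:500, nex - 1L, replace = TRUE)
                   else integer(0)
        gap <- round(stats::rexp(1L, 1 / spec$intergenic_mean)) + 1L
        start <- pos + gap
        ex_start <- integer(nex); ex_end <- integer(nex)
        p <- start
        for (e in seq_len(nex)) {
          ex_start[e] <- p
          ex_end[e] <- p + ex_len[e] - 1L
          p <- ex_end[e] + 1L + if (e < nex) introns[e] else 0L
        }
        end <- ex_end[nex]
        coord[[cid]] <- list(species = sp, chrom = ch, start = start,
                             end = end,
                             strand = sample(c("+", "-"), 1L),
                             exons = cbind(start = ex_start,
                                           end = ex_end))
        pos <- end
      }
    }
  }

  # family anchors (primary and WGD copies of family ancestral genes)
  anchor_ids <- copy_table$copy_id[
    copy_table$anc_id %in% family_anc &
      copy_table$origin %in% c("primary", "wgd")]
  inv_count <- setNames(integer(length(anchor_ids)), anchor_ids)

  # inversion of family-anchor flanking windows (mirror within footprint)
  for (sp in spec$species) {
    for (ch in names(order_by_species[[sp]])) {
      ids <- order_by_species[[sp]][[ch]]
      here <- intersect(anchor_ids, ids)
      for (aid in here) {
        if (stats::runif(1L) >= spec$inversion_rate) next
        a <- coord[[aid]]
        lo <- a$start - spec$window_bp
        hi <- a$end + spec$window_bp
        member <- vapply(ids, function(g)
          coord[[g]]$end >= lo && coord[[g]]$start <= hi, logical(1))
        seg <- range(which(member))
        seg_ids <- ids[seg[1L]:seg[2L]]
        seg_lo <- min(vapply(seg_ids, function(g) coord[[g]]$start,
                             numeric(1)))
        seg_hi <- max(vapply(seg_ids, function(g) coord[[g]]$end,
                             numeric(1)))
        for (g in seg_ids) {
          s <- coord[[g]]$start; e <- coord[[g]]$end
          ex <- coord[[g]]$exons
          coord[[g]]$start <- seg_lo + (seg_hi - e)
          coord[[g]]$end <- seg_lo + (seg_hi - s)
          coord[[g]]$exons <- cbind(
            start = rev(seg_lo + (seg_hi - ex[, "end"])),
            end = rev(seg_lo + (seg_hi - ex[, "start"])))
          coord[[g]]$strand <- if (coord[[g]]$strand == "+") "-" else "+"
        }
        ids <- c(if (seg[1L] > 1L) ids[1:(seg[1L] - 1L)],
                 rev(seg_ids),
                 if (seg[2L] < length(ids)) ids[(seg[2L] + 1L):length(ids)])
        order_by_species[[sp]][[ch]] <- ids
        covered <- intersect(here, seg_ids)
        inv_count[covered] <- inv_count[covered] + 1L
        event_rows[[length(event_rows) + 1L]] <-
          new_event(sp, "inversion", ch, copy_id = aid,
                    from = seg[1L], to = seg[2L])
      }
    }
  }

  # coding sequences evolved independently from each ancestral CDS
  cds <- character(nrow(copy_table))
  names(cds) <- copy_table$copy_id
  for (k in seq_len(nrow(copy_table)))
    cds[k] <- evolve_cds(anc_cds[[copy_table$anc_id[k]]],
                         spec$branch_subs, spec$omega, spec$kappa)
  proteins <- vapply(cds, translate_cds, character(1))

  # assemble the gene table
  all_ids <- names(coord)
  genes <- gene_table(
    gene_id = all_ids,
    species = vapply(coord, `[[`, character(1), "species"),
    seqid = vapply(coord, `[[`, character(1), "chrom"),
    start = vapply(coord, function(x) x$start, numeric(1)),
    end = vapply(coord, function(x) x$end, numeric(1)),
    strand = vapply(coord, `[[`, character(1), "strand"),
    exons = lapply(coord, `[[`, "exons")
  )

  # homolog table: all true homolog pairs, plus optional decoys
  hom <- list()
  for (aid in anc$anc_id) {
    ids <- copy_table$copy_id[copy_table$anc_id == aid]
    if (length(ids) < 2L) next
    cmb <- utils::combn(sort(ids), 2L)
    hom[[aid]] <- data.frame(
      gene_a = cmb[1L, ], gene_b = cmb[2L, ],
      score = round(stats::runif(ncol(cmb), 200, 500), 1),
      evalue = 10^-stats::runif(ncol(cmb), 50, 180),
      stringsAsFactors = FALSE
    )
  }
  homologs <- do.call(rbind, hom)
  rownames(homologs) <- NULL
  if (spec$n_decoys > 0L) {
    decoys <- list()
    tries <- 0L
    while (length(decoys) < spec$n_decoys && tries < 50L * spec$n_decoys) {
      tries <- tries + 1L
      pick <- sample(copy_table$copy_id, 2L)
      if (copy_table$anc_id[match(pick[1L], copy_table$copy_id)] ==
          copy_table$anc_id[match(pick[2L], copy_table$copy_id)]) next
      decoys[[length(decoys) + 1L]] <- data.frame(
        gene_a = min(pick), gene_b = max(pick),
        score = round(stats::runif(1L, 50, 80), 1),
        evalue = 10^-stats::runif(1L, 1, 5),
        stringsAsFactors = FALSE
      )
    }
    homologs <- rbind(homologs, do.call(rbind, decoys))
  }
  homologs <- canonicalize_pairs(homologs)

  # domain hits: every family descendant hits the family domain; some
  # background genes hit an unrelated accession
  fam_copies <- copy_table$copy_id[copy_table$anc_id %in% family_anc]
  prot_len <- nchar(proteins[fam_copies])
  hits <- data.frame(
    gene_id = fam_copies, domain_acc = "PF04873",
    evalue = 10^-stats::runif(length(fam_copies), 20, 100),
    hit_start = 1L, hit_end = pmin(180L, prot_len),
    stringsAsFactors = FALSE
  )
  bg <- setdiff(copy_table$copy_id, fam_copies)
  bg <- bg[stats::runif(length(bg)) < 0.1]
  if (length(bg) > 0L)
    hits <- rbind(hits, data.frame(
      gene_id = bg, domain_acc = "PF99999",
      evalue = 10^-stats::runif(length(bg), 5, 40),
      hit_start = 1L, hit_end = 50L, stringsAsFactors = FALSE))

  ortholog_map <- lapply(setNames(anc$anc_id, anc$anc_id), function(aid) {
    sub <- copy_table[copy_table$anc_id == aid, , drop = FALSE]
    split(sub$copy_id, sub$species)
  })
  event_log <- if (length(event_rows) > 0L) do.call(rbind, event_rows)
    else new_event(character(0), character(0), character(0))[0, ]

  structure(
    list(spec = spec, genes = genes, cds = cds, proteins = proteins,
         homologs = homologs, hits = hits,
         truth = list(
           ancestral = anc, anc_cds = anc_cds,
           copy_table = copy_table, all_copies = all_copies,
           ortholog_map = ortholog_map,
           event_log = event_log,
           inverted_windows = data.frame(
             copy_id = names(inv_count),
             inverted = inv_count %% 2L == 1L,
             stringsAsFactors = FALSE),
           family_anc = family_anc, anchor_ids = anchor_ids,
           true_omega = spec$omega)),
    class = "famsynt_sim"
  )
}

#' @export
print.famsynt_sim <- function(x, ...) {
  cat("Simulated gene complements:", length(x$spec$species), "species,",
      nrow(x$genes), "genes,", nrow(x$homologs), "homolog pairs\n")
  cat("family anchors:", paste(x$truth$anchor_ids, collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate a qRT-PCR Ct table with replicate noise
#'
#' `Ct = baseline - log2(fold_change) + Normal(0, noise_sd)` per
#' replicate; the reference gene's fold change is fixed at 1 in every
#' sample.  With `noise_sd = 0` and fold changes of 1 in the calibrator
#' column, [relative_expression()] recovers the fold changes exactly.
#'
#' @param fold_changes Gene x sample matrix of true relative
#'   quantities (dimnames required).
#' @param reference_gene Reference gene id; appended with fold change 1
#'   everywhere if absent from the matrix.
#' @param noise_sd Replicate noise SD in Ct cycles (>= 0).
#' @param n_replicates Replicates per (gene, sample), default 3.
#' @param baseline Baseline Ct per gene (recycled).
#' @param seed Optional seed.
#' @return data.frame of Ct records (`gene_id`, `sample`, `replicate`,
#'   `ct`).
#' @export
simulate_ct_table <- function(fold_changes, reference_gene,
                              noise_sd = 0.2, n_replicates = 3L,
                              baseline = 25, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(rownames(fold_changes)) || is.null(colnames(fold_changes)))
    stop("fold_changes needs row (gene) and column (sample) names")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  if (!reference_gene %in% rownames(fold_changes)) {
    fold_changes <- rbind(fold_changes,
                          matrix(1, 1L, ncol(fold_changes),
                                 dimnames = list(reference_gene, NULL)))
  } else if (any(fold_changes[reference_gene, ] != 1)) {
    stop("reference gene fold change must be 1 in every sample")
  }
  genes <- rownames(fold_changes)
  samples <- colnames(fold_changes)
  base <- rep_len(baseline, length(genes))
  out <- expand.grid(replicate = seq_len(n_replicates),
                     sample = samples, gene_id = genes,
                     stringsAsFactors = FALSE)
  out <- out[, c("gene_id", "sample", "replicate")]
  out$ct <- base[match(out$gene_id, genes)] -
    log2(fold_changes[cbind(out$gene_id, out$sample)]) +
    stats::rnorm(nrow(out), 0, noise_sd)
  rownames(out) <- NULL
  out
}

#' Write a simulated data set to standard files
#'
#' Emits `genes.gff3`, `cds.fasta`, `proteins.fasta`, `homologs.tsv`,
#' `hits.tsv` and `truth.json` under a directory.
#'
#' @param sim A `famsynt_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_fasta(sim$cds, file.path(dir, "cds.fasta"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  utils::write.table(sim$homologs, file.path(dir, "homologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$hits, file.path(dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$anc_cds <- as.list(truth$anc_cds)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
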