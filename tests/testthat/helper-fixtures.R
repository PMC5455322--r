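# Shared fixture builders.

# gene table laid out like a small chromosome: n genes of width `len`
# separated by `gap` bases
linear_genes <- function(n, seqid = "chr1", species = "S1",
                         gap = 10000L, len = 2000L, prefix = "g") {
  starts <- seq_len(n) * (gap + len)
  gene_table(gene_id = paste0(prefix, seq_len(n)), species = species,
             seqid = seqid, start = starts, end = starts + len - 1L)
}

# homolog table linking gi <-> hi for the given indices
link_pairs <- function(idx_a, idx_b, prefix_a = "g", prefix_b = "h",
                       score = 300) {
  data.frame(gene_a = paste0(prefix_a, idx_a),
             gene_b = paste0(prefix_b, idx_b),
             score = rep_len(score, length(idx_a)),
             evalue = 1e-50, stringsAsFactors = FALSE)
}

# reconstruct the per-chromosome gene orders of a simulation by
# replaying its event log, independently of the generator's bookkeeping
replay_event_log <- function(sim) {
  truth <- sim$truth
  anc <- truth$ancestral
  ac <- truth$all_copies   # includes copies later lost
  log <- truth$event_log
  out <- list()
  for (sp in sim$spec$species) {
    chroms <- list()
    primary <- ac[ac$species == sp & ac$origin == "primary", ]
    for (ch in unique(anc$chrom)) {
      ids <- anc$anc_id[anc$chrom == ch][order(anc$rank[anc$chrom == ch])]
      chroms[[paste0("chr", ch)]] <-
        primary$copy_id[match(ids, primary$anc_id)]
    }
    ev <- log[log$species == sp, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      if (e$type == "wgd") {
        wgd <- ac[ac$species == sp & ac$origin == "wgd" &
                    ac$chrom == e$chrom, ]
        src_anc <- ac$anc_id[match(chroms[[e$parent]], ac$copy_id)]
        chroms[[e$chrom]] <- wgd$copy_id[match(src_anc, wgd$anc_id)]
      } else if (e$type == "tandem") {
        v <- chroms[[e$chrom]]
        i <- match(e$parent, v)
        chroms[[e$chrom]] <- append(v, e$copy_id, after = i)
      } else if (e$type == "loss") {
        chroms[[e$chrom]] <- setdiff(chroms[[e$chrom]], e$copy_id)
      } else if (e$type == "inversion") {
        v <- chroms[[e$chrom]]
        seg <- e$from:e$to
        v[seg] <- rev(v[seg])
        chroms[[e$chrom]] <- v
      }
    }
    out[[sp]] <- chroms
  }
  out
}

# emitted per-chromosome gene orders (by coordinate)
emitted_orders <- function(sim) {
  g <- sim$genes
  out <- list()
  for (sp in unique(g$species)) {
    chroms <- list()
    for (ch in unique(g$seqid[g$species == sp])) {
      sub <- g[g$species == sp & g$seqid == ch, ]
      chroms[[ch]] <- sub$gene_id[order(sub$start)]
    }
    out[[sp]] <- chroms
  }
  out
}

# anchor pairs descending from the same family ancestor (primary/WGD
# copies), as a 2-column matrix
true_anchor_pairs <- function(sim) {
  ct <- sim$truth$copy_table
  out <- NULL
  for (a in sim$truth$family_anc) {
    ids <- sort(ct$copy_id[ct$anc_id == a &
                             ct$origin %in% c("primary", "wgd")])
    if (length(ids) >= 2L) out <- rbind(out, t(utils::combn(ids, 2L)))
  }
  out
}
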