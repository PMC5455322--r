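test_that("simulation is deterministic given its seed", {
  s1 <- simulate_genomes(sim_spec(seed = 5))
  s2 <- simulate_genomes(sim_spec(seed = 5))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$homologs, s2$homologs)
  s3 <- simulate_genomes(sim_spec(seed = 6))
  expect_false(identical(s1$cds, s3$cds))
})

test_that("WGD species carry two copies of every surviving gene", {
  spec <- sim_spec(wgd_species = "S1", loss_rate = 0, tandem_rate = 0,
                   seed = 2)
  sim <- simulate_genomes(spec)
  ct <- sim$truth$copy_table
  per_anc <- table(ct$anc_id[ct$species == "S1"])
  expect_true(all(per_anc == 2L))
  for (sp in c("S2", "S3", "S4"))
    expect_true(all(table(ct$anc_id[ct$species == sp]) == 1L))
  # WGD copies live on distinct chromosomes from their primaries
  prim <- ct[ct$species == "S1" & ct$origin == "primary", ]
  wgd <- ct[ct$species == "S1" & ct$origin == "wgd", ]
  expect_length(intersect(unique(prim$chrom), unique(wgd$chrom)), 0L)
})

test_that("tandem duplicates are rank-adjacent on their own chromosome", {
  spec <- sim_spec(tandem_rate = 1, wgd_species = character(0),
                   loss_rate = 0, inversion_rate = 0, seed = 3)
  sim <- simulate_genomes(spec)
  ct <- sim$truth$copy_table
  g <- sim$genes
  tand <- ct[ct$origin == "tandem", ]
  expect_gt(nrow(tand), 0L)
  for (k in seq_len(nrow(tand))) {
    sib <- ct$copy_id[ct$anc_id == tand$anc_id[k] &
                        ct$species == tand$species[k] &
                        ct$origin == "primary"]
    sub <- g[g$species == tand$species[k] & g$seqid == tand$chrom[k], ]
    ord <- sub$gene_id[order(sub$start)]
    expect_equal(abs(match(tand$copy_id[k], ord) - match(sib, ord)), 1L)
  }
})

test_that("excessive loss aborts with advice", {
  expect_error(
    simulate_genomes(sim_spec(loss_rate = 1, seed = 1)),
    "fewer than 3 genes"
  )
})

test_that("replaying the event log reproduces the emitted gene orders", {
  sim <- simulate_genomes(sim_spec(tandem_rate = 0.2, loss_rate = 0.1,
                                   inversion_rate = 0.5, seed = 13))
  replayed <- replay_event_log(sim)
  emitted <- emitted_orders(sim)
  for (sp in names(emitted))
    for (ch in names(emitted[[sp]]))
      expect_identical(replayed[[sp]][[ch]], emitted[[sp]][[ch]])
})

test_that("every emitted gene appears exactly once in the ortholog map", {
  sim <- simulate_genomes(sim_spec(tandem_rate = 0.2, loss_rate = 0.1,
                                   seed = 17))
  mapped <- unlist(sim$truth$ortholog_map, use.names = FALSE)
  expect_setequal(mapped, sim$genes$gene_id)
  expect_false(anyDuplicated(mapped) > 0L)
})

test_that("codon evolution honours omega and branch length limits", {
  set.seed(31)
  anc <- random_cds(200)
  # omega = 0: only synonymous changes, translation preserved
  p0 <- evolve_codon_pair(anc, 0.2, omega = 0, seed = 8)
  expect_false(identical(p0$a, anc))
  expect_identical(translate_cds(p0$a), translate_cds(anc))
  expect_identical(translate_cds(p0$b), translate_cds(anc))
  # branch_subs = 0: descendants equal the ancestor
  pz <- evolve_codon_pair(anc, 0, omega = 0.5, seed = 8)
  expect_identical(pz$a, anc)
  expect_identical(pz$b, anc)
  # ancestral stop codons are rejected
  expect_error(evolve_cds(paste0("TAA", anc), 0.1, 0.5), "stop codon")
  # determinism under seed
  expect_identical(evolve_codon_pair(anc, 0.1, 0.3, seed = 4),
                   evolve_codon_pair(anc, 0.1, 0.3, seed = 4))
})

test_that("NG86 on evolved pairs is consistent as length grows", {
  set.seed(55)
  bias <- vapply(c(100L, 800L), function(len) {
    anc <- random_cds(len)
    est <- vapply(1:30, function(i) {
      p <- evolve_codon_pair(anc, 0.2, omega = 0.2, seed = 100 + i)
      suppressWarnings(ng86(p$a, p$b)$ratio)
    }, numeric(1))
    abs(median(est, na.rm = TRUE) - 0.2)
  }, numeric(1))
  expect_lt(bias[2], 0.08)
  expect_lte(bias[2], bias[1] + 0.02)
})

test_that("Ct simulation is deterministic, validated, and invertible", {
  fc <- matrix(c(1, 2, 1, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("root", "leaf")))
  expect_error(simulate_ct_table(fc, "TUB", noise_sd = -1), "noise_sd")
  t1 <- simulate_ct_table(fc, "TUB", noise_sd = 0.3, seed = 9)
  t2 <- simulate_ct_table(fc, "TUB", noise_sd = 0.3, seed = 9)
  expect_identical(t1, t2)
  expect_equal(sum(t1$gene_id == "g1" & t1$sample == "root"), 3L)
  clean <- simulate_ct_table(fc, "TUB", noise_sd = 0, seed = 1)
  em <- relative_expression(clean, "TUB", "root")
  expect_equal(em$rq[c("g1", "g2"), "leaf"], c(g1 = 2, g2 = 4))
  # fold change 1 everywhere -> all relative quantities 1
  flat <- matrix(1, 2, 2, dimnames = dimnames(fc))
  emf <- relative_expression(simulate_ct_table(flat, "TUB", noise_sd = 0),
                             "TUB", "root")
  expect_true(all(abs(emf$rq - 1) < 1e-12))
})
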