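test_that("flank regions use closed-interval span intersection", {
  genes <- gene_table(
    gene_id = c("anchor", "at_edge", "past_edge", "inside", "elsewhere"),
    species = "S1",
    seqid = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(50000L, 151999L, 152001L, 90000L, 50000L),
    end = c(52000L, 153000L, 153500L, 91000L, 52000L)
  )
  reg <- extract_flank_region("anchor", genes, window_bp = 100000L)
  # at_edge starts exactly at anchor.end + 100000 -> included
  expect_true("at_edge" %in% reg$genes$gene_id)
  expect_false("past_edge" %in% reg$genes$gene_id)
  expect_true("inside" %in% reg$genes$gene_id)
  expect_false("elsewhere" %in% reg$genes$gene_id)
  expect_error(extract_flank_region("nope", genes), "not found")
  solo <- gene_table("lonely", "S1", "scaf9", 100L, 900L)
  reg2 <- extract_flank_region("lonely", solo)
  expect_equal(reg2$genes$gene_id, "lonely")
})

test_that("block calling enforces the three-pair threshold", {
  ga <- linear_genes(5, prefix = "g", species = "S1")
  gb <- linear_genes(5, prefix = "h", species = "S2")
  genes <- rbind(ga, gb)
  class(genes) <- class(ga)
  ra <- extract_flank_region("g3", genes)
  rb <- extract_flank_region("h3", genes)
  expect_null(call_block(ra, rb, link_pairs(1:2, 1:2)))
  b3 <- call_block(ra, rb, link_pairs(1:3, 1:3))
  expect_s3_class(b3, "syntenic_block")
  expect_equal(nrow(b3$matched_pairs), 3L)
  expect_false(b3$is_intraspecies)
})

test_that("matching is one-to-one and equals brute-force maximum", {
  ga <- linear_genes(4, prefix = "g", species = "S1")
  gb <- linear_genes(4, prefix = "h", species = "S2")
  genes <- rbind(ga, gb); class(genes) <- class(ga)
  ra <- extract_flank_region("g2", genes)
  rb <- extract_flank_region("h2", genes)
  # g1 homologous to two genes in the other region: counted once
  hom <- rbind(link_pairs(c(1, 1, 2, 3), c(1, 2, 3, 4)))
  blk <- call_block(ra, rb, hom, min_pairs = 1L)
  expect_equal(nrow(blk$matched_pairs), 3L)
  expect_false(anyDuplicated(c(blk$matched_pairs$gene_a,
                               blk$matched_pairs$gene_b)) > 0)
  # matching equals the brute-force maximum on random toy instances
  set.seed(12)
  for (i in 1:20) {
    m <- sample(3:6, 1L)
    hom_r <- unique(link_pairs(sample(4, m, TRUE), sample(4, m, TRUE)))
    hom_r$score <- runif(nrow(hom_r), 100, 500)
    blk_r <- call_block(ra, rb, hom_r, min_pairs = 1L)
    got <- if (is.null(blk_r)) 0L else nrow(blk_r$matched_pairs)
    expect_equal(got, oracle_max_matching(hom_r$gene_a, hom_r$gene_b))
  }
})

test_that("block calling and quality are symmetric in their regions", {
  ga <- linear_genes(6, prefix = "g", species = "S1")
  gb <- linear_genes(8, prefix = "h", species = "S2")
  genes <- rbind(ga, gb); class(genes) <- class(ga)
  ra <- extract_flank_region("g3", genes)
  rb <- extract_flank_region("h4", genes)
  hom <- link_pairs(c(1, 3, 5), c(2, 4, 6))
  ab <- call_block(ra, rb, hom)
  ba <- call_block(rb, ra, hom)
  expect_setequal(paste(ab$matched_pairs$gene_a, ab$matched_pairs$gene_b),
                  paste(ba$matched_pairs$gene_b, ba$matched_pairs$gene_a))
  expect_equal(block_quality(ab)$q, block_quality(ba)$q)
  expect_equal(detect_orientation(ab), detect_orientation(ba))
})

test_that("orientation follows the sign of the rank correlation", {
  ga <- linear_genes(3, prefix = "g", species = "S1")
  gb <- linear_genes(3, prefix = "h", species = "S2")
  genes <- rbind(ga, gb); class(genes) <- class(ga)
  ra <- extract_flank_region("g2", genes)
  rb <- extract_flank_region("h2", genes)
  col <- call_block(ra, rb, link_pairs(1:3, 1:3))
  expect_equal(detect_orientation(col), "collinear")
  inv <- call_block(ra, rb, link_pairs(1:3, 3:1))
  expect_equal(detect_orientation(inv), "inverted")
  one <- call_block(ra, rb, link_pairs(1, 1), min_pairs = 1L)
  expect_error(detect_orientation(one), "2 matched pairs")
})

test_that("groups are connected components of the block graph", {
  mk_block <- function(a, b) structure(
    list(region_a = list(anchor = a), region_b = list(anchor = b),
         matched_pairs = NULL, is_intraspecies = FALSE),
    class = "syntenic_block")
  grp <- build_groups(list(mk_block("A", "B"), mk_block("B", "C")))
  expect_equal(grp, list(c("A", "B", "C")))
  expect_equal(build_groups(list()), list())
  two <- build_groups(list(mk_block("A", "B"), mk_block("X", "Y")))
  expect_length(two, 2L)
  expect_setequal(unlist(two), c("A", "B", "X", "Y"))
})

test_that("syntenic quality follows 2m/(n1+n2)", {
  expect_equal(syntenic_quality(3, 10, 14)$q, 25)
  expect_equal(syntenic_quality(0, 5, 7)$q, 0)
  expect_equal(syntenic_quality(6, 6, 6)$q, 100)
  expect_error(syntenic_quality(5, 4, 10), "exceeds")
  expect_error(syntenic_quality(0, 0, 0), "undefined")
})

test_that("aggregation reproduces per-pair and grand means", {
  q <- c(22.50, 44.07, 26.67, 40.00, 29.73)
  pair <- c("Pb-Pp", "Pb-Pp", "Pp-Pm", "Pp-Pm", "Pp-Pm")
  clade <- c("B1", "B2", "A1", "B1", "B2")
  agg <- aggregate_quality(q, pair, clade)
  expect_true(abs(agg$pair_means[["Pb-Pp"]] - 33.29) <= 0.005 + 1e-9)
  expect_true(abs(agg$pair_means[["Pp-Pm"]] - 32.13) <= 0.005 + 1e-9)
  expect_equal(agg$grand_mean, mean(agg$pair_means))
  empty <- aggregate_quality(numeric(0), character(0), character(0))
  expect_true(is.na(empty$grand_mean))
})

test_that("widening the window never loses matched pairs", {
  sim <- simulate_genomes(sim_spec(loss_rate = 0, tandem_rate = 0,
                                   inversion_rate = 0, seed = 23))
  pairs <- true_anchor_pairs(sim)[1:4, , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    prev <- 0L
    for (w in c(25000L, 50000L, 100000L, 200000L)) {
      ra <- extract_flank_region(pairs[k, 1], sim$genes, w)
      rb <- extract_flank_region(pairs[k, 2], sim$genes, w)
      blk <- call_block(ra, rb, sim$homologs, min_pairs = 1L)
      m <- if (is.null(blk)) 0L else nrow(blk$matched_pairs)
      expect_gte(m, prev)
      prev <- m
    }
  }
})

test_that("tandem versus WGD/segmental classification uses gene ranks", {
  genes <- gene_table(
    gene_id = c("a", "b", "c", "d", "e"), species = "S1",
    seqid = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 9000L, 50000L, 1000L),
    end = c(2000L, 6000L, 10000L, 51000L, 2000L)
  )
  expect_equal(classify_duplication_mode("a", "b", genes), "tandem")
  expect_equal(classify_duplication_mode("a", "c", genes), "tandem")
  expect_equal(classify_duplication_mode("a", "d", genes),
               "WGD_or_segmental")
  expect_equal(classify_duplication_mode("a", "e", genes),
               "WGD_or_segmental")
})
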