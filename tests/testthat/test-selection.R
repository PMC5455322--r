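test_that("NG86 reproduces the hand-worked single-difference case", {
  a <- strrep("AAA", 12)
  b <- paste0(strrep("AAA", 11), "AAG")
  r <- ng86(a, b)
  expect_equal(r$S, 4)
  expect_equal(r$N, 32)
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$ks, 0.304099, tolerance = 1e-6)
  expect_equal(r$ka, 0)
})

test_that("identical sequences give zero rates and undefined ratio", {
  a <- "ATGAAACCCGGG"
  r <- ng86(a, a)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$ratio))
})

test_that("tiny synonymous-site counts trigger the saturation flag", {
  # AAA->AAG is synonymous but the two codons carry only 1/3 syn site
  # each; with an ATG partner S = 1/3, so pS = 3 >= 3/4
  r <- suppressWarnings(ng86("AAAATG", "AAGATG"))
  expect_true(r$saturated_s)
  expect_true(is.na(r$ks))
})

test_that("NG86 matches the pathway-enumeration oracle", {
  set.seed(1234)
  for (i in 1:200) {
    fx <- random_codon_fixture(n_codons = sample(3:10, 1L),
                               n_mut = sample(0:5, 1L))
    mine <- suppressWarnings(ng86(fx$a, fx$b))
    ref <- oracle_ng86(fx$a, fx$b)
    expect_equal(mine$S, ref$S, tolerance = 1e-12)
    expect_equal(mine$N, ref$N, tolerance = 1e-12)
    expect_equal(mine$sd, ref$sd, tolerance = 1e-12)
    expect_equal(mine$nd, ref$nd, tolerance = 1e-12)
    expect_equal(mine$ks, ref$ks, tolerance = 1e-12)
    expect_equal(mine$ka, ref$ka, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric and conserves site counts", {
  set.seed(77)
  for (i in 1:25) {
    fx <- random_codon_fixture(n_codons = 12, n_mut = 4)
    ab <- suppressWarnings(ng86(fx$a, fx$b))
    ba <- suppressWarnings(ng86(fx$b, fx$a))
    expect_equal(ab$ka, ba$ka)
    expect_equal(ab$ks, ba$ks)
    expect_equal(ab$S + ab$N, 3 * ab$n_codons)
  }
})

test_that("gapped and ambiguous codon columns are excluded pairwise", {
  r <- ng86("ATG---AAA", "ATGCCCAAA")
  expect_equal(r$n_codons, 2L)
  r2 <- ng86("ATGNNNAAA", "ATGCCCAAA")
  expect_equal(r2$n_codons, 2L)
  expect_error(ng86("---", "---"), "no comparable")
})

test_that("window counting follows the exact formula", {
  expect_equal(n_windows(300), 17L)  # floor((300-150)/9)+1
  expect_equal(n_windows(150), 1L)
  expect_equal(n_windows(149), 0L)
  for (L in seq(150L, 600L, 3L))
    expect_equal(n_windows(L), (L - 150L) %/% 9L + 1L)
})

test_that("sliding windows scan the whole aligned length", {
  set.seed(10)
  anc <- random_cds(100)  # 300 nt
  pair <- evolve_codon_pair(anc, 0.1, 0.3, seed = 3)
  prof <- sliding_window(pair$a, pair$b)
  expect_equal(nrow(prof), 17L)
  expect_equal(prof$start[1], 1L)
  expect_equal(prof$end[nrow(prof)], 294L)
  # identical pair: zero everywhere
  flat <- sliding_window(anc, anc)
  expect_true(all(flat$ka == 0 & flat$ks == 0))
  expect_warning(sliding_window("ATGAAA", "ATGAAA"), "shorter")
})

test_that("a two-regime alignment shows the 5'-purifying gradient", {
  set.seed(202)
  h1 <- random_cds(300)
  h2 <- random_cds(300)
  p1 <- evolve_codon_pair(h1, 0.15, omega = 0.05, seed = 41)
  p2 <- evolve_codon_pair(h2, 0.15, omega = 0.8, seed = 42)
  a <- paste0(p1$a, p2$a)
  b <- paste0(p1$b, p2$b)
  prof <- sliding_window(a, b)
  half <- nchar(a) / 2
  five_prime <- prof$ratio[prof$end <= half]
  three_prime <- prof$ratio[prof$start > half]
  expect_lt(mean(five_prime, na.rm = TRUE),
            mean(three_prime, na.rm = TRUE))
})

test_that("selection regimes classify by the unit ratio", {
  expect_equal(classify_selection(c(0.4, 2, 1, NA)),
               c("purifying", "positive", "neutral", "undefined"))
  expect_equal(classify_selection(1 + 1e-12), "neutral")
})

test_that("mean flanking Ks averages usable non-anchor pairs", {
  mk_region <- function(anchor, ids) {
    g <- linear_genes(length(ids), prefix = "x")
    g$gene_id <- ids
    structure(list(anchor = anchor, species = "S1", seqid = "chr1",
                   genes = g, window_bp = 100000L),
              class = "flank_region")
  }
  # three flanking pairs with engineered Ks plus the anchor pair
  anc1 <- random_cds(200); anc2 <- random_cds(200); anc3 <- random_cds(150)
  set.seed(5)
  p1 <- evolve_codon_pair(anc1, 0.05, 0.2, seed = 1)
  p2 <- evolve_codon_pair(anc2, 0.10, 0.2, seed = 2)
  p3 <- evolve_codon_pair(anc3, 0.15, 0.2, seed = 3)
  cds <- c(a1 = p1$a, b1 = p1$b, a2 = p2$a, b2 = p2$b,
           a3 = p3$a, b3 = p3$b, anchA = random_cds(100),
           anchB = random_cds(100))
  block <- structure(list(
    region_a = mk_region("anchA", c("anchA", "a1", "a2", "a3")),
    region_b = mk_region("anchB", c("anchB", "b1", "b2", "b3")),
    matched_pairs = data.frame(
      gene_a = c("anchA", "a1", "a2", "a3"),
      gene_b = c("anchB", "b1", "b2", "b3"),
      score = 300, evalue = 1e-50, stringsAsFactors = FALSE),
    is_intraspecies = FALSE), class = "syntenic_block")
  res <- mean_flanking_ks(block, cds)
  expect_equal(res$n_pairs, 3L)
  manual <- vapply(list(p1, p2, p3), function(p)
    suppressWarnings(ng86(p$a, p$b)$ks), numeric(1))
  expect_equal(res$mean_ks, mean(manual))
  # length-mismatched CDS is skipped with a warning
  cds2 <- cds
  cds2[["a2"]] <- paste0(cds2[["a2"]], "AAA")
  expect_warning(res2 <- mean_flanking_ks(block, cds2), "skipped")
  expect_equal(res2$n_pairs, 2L)
  expect_equal(res2$mean_ks, mean(manual[c(1, 3)]))
})

test_that("Ks epochs date duplications by closed intervals", {
  expect_equal(date_duplication(c(0.17, 1.6, 0.8)),
               c("recent_WGD", "ancient_WGD", "unassigned"))
  expect_equal(date_duplication(c(0.15, 0.3, 1.5, 1.8)),
               c("recent_WGD", "recent_WGD", "ancient_WGD",
                 "ancient_WGD"))
  expect_equal(date_duplication(c(0.1499, 0.3001, NA)),
               rep("unassigned", 3))
})

test_that("back-translation expands residues to codons and gaps to ---", {
  cds <- c(x = "ATGAAA", y = "ATGAAA")
  aln <- c(x = "MK-", y = "M-K")
  bt <- backtranslate(aln, cds)
  expect_identical(bt[["x"]], "ATGAAA---")
  expect_identical(bt[["y"]], "ATG---AAA")
  expect_identical(gsub("-", "", bt[["x"]]), cds[["x"]])
  # identical rows -> no gaps
  bt2 <- backtranslate(c(x = "MK", y = "MK"), cds)
  expect_false(any(grepl("-", bt2)))
  # trailing stop codons are tolerated
  bt3 <- backtranslate(c(x = "MK"), c(x = "ATGAAATAA"))
  expect_identical(bt3[["x"]], "ATGAAA")
  # mismatching CDS is refused with a position
  expect_error(backtranslate(c(x = "MR"), cds), "residue 2")
})
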