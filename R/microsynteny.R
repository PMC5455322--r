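## Family-anchored microsynteny: flanking-region extraction, block
## calling, orientation, group assembly, and the relative
## syntenic-quality statistic with its aggregation scheme.

#' Extract the flanking region around an anchor gene
#'
#' A gene belongs to the region iff it lies on the anchor's seqid (and
#' species) and its span intersects the closed interval
#' `[anchor.start - window_bp, anchor.end + window_bp]` — the protein-
#' coding genes within the window upstream and downstream of the anchor.
#'
#' @param anchor Gene id of the anchor (a family member).
#' @param genes A `gene_table` containing the anchor.
#' @param window_bp Window size on each side (default 100000).
#' @return Object of class `flank_region`: list with `anchor`,
#'   `species`, `seqid`, `genes` (rows sorted by start), `window_bp`.
#' @export
extract_flank_region <- function(anchor, genes, window_bp = 100000L) {
  i <- match(anchor, genes$gene_id)
  if (is.na(i)) stop("anchor '", anchor, "' not found among gene models")
  lo <- genes$start[i] - window_bp
  hi <- genes$end[i] + window_bp
  same <- genes$seqid == genes$seqid[i] &
    (is.na(genes$species[i]) | genes$species == genes$species[i])
  hit <- same & genes$end >= lo & genes$start <= hi
  reg <- genes[hit, , drop = FALSE]
  reg <- reg[order(reg$start, reg$gene_id), , drop = FALSE]
  rownames(reg) <- NULL
  structure(
    list(anchor = anchor, species = genes$species[i],
         seqid = genes$seqid[i], genes = reg, window_bp = window_bp),
    class = "flank_region"
  )
}

#' @export
print.flank_region <- function(x, ...) {
  cat("Flanking region around", x$anchor, "(", x$seqid, "):",
      nrow(x$genes), "genes within +/-", x$window_bp, "bp\n")
  invisible(x)
}

#' Call a syntenic block between two flanking regions
#'
#' Homolog pairs with one gene in each region are matched one-to-one by
#' maximum-cardinality bipartite matching (augmenting paths, seeded and
#' tie-broken by descending score then canonical pair ids, so the
#' result is deterministic and agrees with a brute-force maximum
#' matcher), and a block is returned iff at least `min_pairs` matches
#' remain — the "three or more conserved homologs" definition.  The
#' call is symmetric in its two regions.
#'
#' @param region_a,region_b `flank_region` objects.
#' @param homologs data.frame of homolog pairs (`gene_a`, `gene_b`,
#'   `score`, `evalue`), canonicalized as by [read_homolog_table()].
#' @param min_pairs Minimum matched pairs (default 3).
#' @return Object of class `syntenic_block` (with `region_a`,
#'   `region_b`, `matched_pairs`, `is_intraspecies`), or `NULL` when no
#'   block is supported.
#' @export
call_block <- function(region_a, region_b, homologs, min_pairs = 3L) {
  ga <- region_a$genes$gene_id
  gb <- region_b$genes$gene_id
  in_a <- homologs$gene_a %in% ga & homologs$gene_b %in% gb
  in_b <- homologs$gene_a %in% gb & homologs$gene_b %in% ga
  cand <- homologs[in_a | in_b, , drop = FALSE]
  cand <- cand[cand$gene_a != cand$gene_b, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$score, cand$gene_a, cand$gene_b), ,
               drop = FALSE]
  # orient each pair as (gene in region_a, gene in region_b)
  flip <- !(cand$gene_a %in% ga)
  tmp <- cand$gene_a[flip]
  cand$gene_a[flip] <- cand$gene_b[flip]
  cand$gene_b[flip] <- tmp
  matched <- cand[max_matching(cand$gene_a, cand$gene_b), , drop = FALSE]
  # a gene occurring in both regions (overlapping intraspecies
  # regions) may be matched on both sides; keep its best pair only
  used <- character(0)
  keep <- logical(nrow(matched))
  for (k in seq_len(nrow(matched))) {
    if (matched$gene_a[k] %in% used || matched$gene_b[k] %in% used) next
    keep[k] <- TRUE
    used <- c(used, matched$gene_a[k], matched$gene_b[k])
  }
  matched <- matched[keep, , drop = FALSE]
  if (nrow(matched) < min_pairs) return(NULL)
  matched <- matched[order(match(matched$gene_a, ga)), , drop = FALSE]
  rownames(matched) <- NULL
  structure(
    list(region_a = region_a, region_b = region_b,
         matched_pairs = matched,
         is_intraspecies = identical(region_a$species,
                                     region_b$species)),
    class = "syntenic_block"
  )
}

# Maximum-cardinality bipartite matching (Kuhn's augmenting paths)
# between the left vertices `a` and right vertices `b` of the edge list
# (a[k], b[k]).  Edges are expected pre-sorted by preference (descending
# score), which seeds the matching greedily and makes the result
# deterministic.  Returns the indices of the matched edges.
max_matching <- function(a, b) {
  left <- unique(a)
  edge_of <- split(seq_along(a), factor(a, levels = left))
  match_b <- setNames(rep(NA_integer_, length(unique(b))), unique(b))
  env <- new.env(parent = emptyenv())
  env$match_b <- match_b
  try_augment <- function(u) {
    for (k in edge_of[[u]]) {
      v <- b[k]
      if (v %in% env$visited) next
      env$visited <- c(env$visited, v)
      cur <- env$match_b[[v]]
      if (is.na(cur) || try_augment(a[cur])) {
        env$match_b[[v]] <- k
        return(TRUE)
      }
    }
    FALSE
  }
  for (u in left) {
    env$visited <- character(0)
    try_augment(u)
  }
  sort(unname(env$match_b[!is.na(env$match_b)]))
}

#' @export
print.syntenic_block <- function(x, ...) {
  cat("Syntenic block ", x$region_a$anchor, " ~ ", x$region_b$anchor,
      ": ", nrow(x$matched_pairs), " matched pairs (",
      if (x$is_intraspecies) "intraspecies" else "interspecies", ")\n",
      sep = "")
  invisible(x)
}

#' Orientation of a syntenic block
#'
#' Spearman rank correlation of the matched genes' positions in the two
#' regions: non-negative correlation is collinear, negative is an
#' inverted arrangement (inverted duplication when intraspecies).
#'
#' @param block A `syntenic_block` with at least 2 matched pairs.
#' @return `"collinear"` or `"inverted"`.
#' @export
detect_orientation <- function(block) {
  m <- block$matched_pairs
  if (nrow(m) < 2L) stop("need at least 2 matched pairs")
  ra <- match(m$gene_a, block$region_a$genes$gene_id)
  rb <- match(m$gene_b, block$region_b$genes$gene_id)
  rho <- suppressWarnings(stats::cor(ra, rb, method = "spearman"))
  if (is.na(rho) || rho >= 0) "collinear" else "inverted"
}

#' Assemble syntenic blocks into microsynteny groups
#'
#' Groups are the connected components of the graph whose vertices are
#' flanking regions (identified by their anchors) and whose edges are
#' blocks; intraspecies and interspecies blocks both contribute.
#'
#' @param blocks List of `syntenic_block` objects.
#' @return List of character vectors of anchor ids, one per group,
#'   ordered by first anchor.
#' @export
build_groups <- function(blocks) {
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0L) return(list())
  edges <- do.call(rbind, lapply(blocks, function(b)
    c(b$region_a$anchor, b$region_b$anchor)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(x) sort(unique(x)))
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

#' Relative syntenic quality of a region pair
#'
#' Twice the number of matches divided by the sum of the total numbers
#' of genes in the two conserved regions, expressed as a percentage.
#'
#' @param m Number of matched homolog pairs.
#' @param n1,n2 Total protein-coding genes in the two regions (anchors
#'   included).
#' @return List with `m`, `n1`, `n2` and `q` (percent).
#' @export
syntenic_quality <- function(m, n1, n2) {
  if (n1 + n2 <= 0) stop("undefined quality: n1 + n2 must be positive")
  if (m > min(n1, n2))
    stop("m (", m, ") exceeds the smaller region size (", min(n1, n2), ")")
  list(m = m, n1 = n1, n2 = n2, q = 100 * 2 * m / (n1 + n2))
}

#' Syntenic quality of a called block
#'
#' @param block A `syntenic_block`.
#' @return As [syntenic_quality()], with `m` the matched pairs and
#'   `n1`, `n2` the regions' gene counts.
#' @export
block_quality <- function(block) {
  syntenic_quality(nrow(block$matched_pairs),
                   nrow(block$region_a$genes),
                   nrow(block$region_b$genes))
}

#' Aggregate per-block syntenic qualities the way Table-style summaries do
#'
#' Cell values are means over blocks sharing a (species pair, clade)
#' combination; each species pair's mean is the unweighted mean over its
#' populated clade cells; the grand mean is the unweighted mean over the
#' per-pair means.
#'
#' @param quality Numeric vector of per-block qualities (percent).
#' @param pair Species-pair label per block (e.g. `"Pb-Pp"`).
#' @param clade Clade/class label per block (e.g. `"B1"`).
#' @return List with `cells` (pair x clade matrix of means, `NA` for
#'   empty cells), `pair_means` (named vector) and `grand_mean`.
#' @export
aggregate_quality <- function(quality, pair, clade) {
  if (length(quality) == 0L)
    return(list(cells = matrix(numeric(0), 0, 0),
                pair_means = setNames(numeric(0), character(0)),
                grand_mean = NA_real_))
  stopifnot(length(pair) == length(quality),
            length(clade) == length(quality))
  pairs <- unique(pair)
  clades <- unique(clade)
  cells <- matrix(NA_real_, length(pairs), length(clades),
                  dimnames = list(pairs, clades))
  for (p in pairs) for (cl in clades) {
    v <- quality[pair == p & clade == cl]
    if (length(v) > 0L) cells[p, cl] <- mean(v)
  }
  pair_means <- apply(cells, 1L, function(row) mean(row, na.rm = TRUE))
  list(cells = cells, pair_means = pair_means,
       grand_mean = mean(pair_means))
}

#' Classify a duplicate gene pair as tandem or WGD/segmental
#'
#' Tandem iff the two genes lie on the same seqid of the same species
#' with at most one intervening gene in positional rank; every other
#' duplicate pair is a whole-genome/segmental duplication candidate.
#'
#' @param gene_a,gene_b Gene ids.
#' @param genes A `gene_table` containing both genes.
#' @return `"tandem"` or `"WGD_or_segmental"`.
#' @export
classify_duplication_mode <- function(gene_a, gene_b, genes) {
  ia <- match(gene_a, genes$gene_id)
  ib <- match(gene_b, genes$gene_id)
  if (is.na(ia) || is.na(ib)) stop("gene not found among gene models")
  if (!identical(genes$species[ia], genes$species[ib]) ||
      genes$seqid[ia] != genes$seqid[ib])
    return("WGD_or_segmental")
  on_chr <- which(genes$seqid == genes$seqid[ia] &
                    (is.na(genes$species[ia]) |
                       genes$species == genes$species[ia]))
  ord <- on_chr[order(genes$start[on_chr], genes$gene_id[on_chr])]
  ranks <- match(c(gene_a, gene_b), genes$gene_id[ord])
  if (abs(ranks[1L] - ranks[2L]) <= 2L) "tandem" else "WGD_or_segmental"
}
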