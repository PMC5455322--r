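## Poisson-corrected protein distances under pairwise deletion,
## neighbor-joining, and the Felsenstein column bootstrap.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Pairwise p-distance under pairwise deletion
#'
#' Sites where either sequence has a gap or ambiguity character (anything
#' outside the 20 amino-acid letters) are excluded for this pair only.
#'
#' @param a,b Aligned amino-acid strings of equal length.
#' @return List with `p` (proportion of differences, `NA` when no site
#'   is comparable) and `n_sites` (compared sites).
#' @export
pairwise_p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in aligned length")
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  ok <- ca %in% AA_ALPHABET & cb %in% AA_ALPHABET
  n <- sum(ok)
  if (n == 0L) return(list(p = NA_real_, n_sites = 0L))
  list(p = sum(ca[ok] != cb[ok]) / n, n_sites = n)
}

#' Poisson correction of a p-distance
#'
#' @param p Proportion(s) of amino-acid differences in `[0, 1)`.
#' @return `d = -log(1 - p)`; `NA` when `p >= 1` or `p` is `NA`.
#' @export
poisson_correct <- function(p) {
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 1
  d[ok] <- -log(1 - p[ok])
  d
}

#' Poisson-corrected distance matrix from a protein alignment
#'
#' @param alignment Named character vector of equal-length aligned
#'   amino-acid sequences.
#' @return List with `d` (symmetric distance matrix, `NA` marks
#'   undefined pairs), `p` and `n_sites` matrices.
#' @export
poisson_distance <- function(alignment) {
  ids <- names(alignment)
  if (is.null(ids)) stop("alignment rows must be named")
  n <- length(alignment)
  d <- p <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ns[i, i] <- nchar(alignment[[i]])
    for (j in seq_len(n)) {
      if (j <= i) next
      pd <- pairwise_p_distance(alignment[[i]], alignment[[j]])
      p[i, j] <- p[j, i] <- pd$p
      ns[i, j] <- ns[j, i] <- pd$n_sites
      d[i, j] <- d[j, i] <- poisson_correct(pd$p)
    }
  }
  list(d = d, p = p, n_sites = ns)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining: at each step the pair
#' minimizing the Q criterion is joined, with ties broken by the lowest
#' (row, column) index pair so the result is deterministic for a given
#' input order.  Returns the unrooted tree (basal trifurcation) as an
#' `ape` `phylo` object.
#'
#' @param d Symmetric numeric matrix with row/column names; all
#'   off-diagonal entries must be defined.
#' @return An object of class `phylo`.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix")
  labels <- rownames(d)
  if (is.null(labels)) stop("d must have row names")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) {
    idx <- sort(which(is.na(d), arr.ind = TRUE)[1L, ])
    stop("undefined distance between '", labels[idx[1L]], "' and '",
         labels[idx[2L]], "'")
  }
  fmt <- function(x) sprintf("%.12g", x)
  sub <- labels  # newick substring per active cluster
  D <- d
  while (length(sub) > 3L) {
    m <- length(sub)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest (row, col) pair among the minima, row-major, i < j
    best <- NULL
    qmin <- min(Q)
    for (i in seq_len(m - 1L)) {
      j <- which(Q[i, (i + 1L):m] == qmin)
      if (length(j) > 0L) { best <- c(i, i + j[1L]); break }
    }
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    new_sub <- paste0("(", sub[i], ":", fmt(bi), ",", sub[j], ":",
                      fmt(bj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", fmt(b1), ",", sub[2], ":", fmt(b2),
                ",", sub[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Felsenstein bootstrap: alignment columns are resampled with
#' replacement, the full pipeline (p-distance under pairwise deletion ->
#' Poisson correction -> neighbor joining) is rerun per replicate, and
#' each internal edge of the full-data tree is annotated with the
#' percentage of replicates containing that bipartition.
#'
#' @param alignment Named character vector of aligned amino-acid
#'   sequences.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; fixing it makes supports
#'   reproducible.
#' @return `phylo` tree with `node.label` holding supports in
#'   `[0, 100]` (`NA` on the basal node and on replicates that could
#'   not be computed).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L,
                              seed = NULL) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  tree <- neighbor_joining(poisson_distance(alignment)$d)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  reps <- vector("list", n_replicates)
  n_ok <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    aln_r <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste,
                            collapse = ""), rownames(mat))
    t_r <- tryCatch(neighbor_joining(poisson_distance(aln_r)$d),
                    error = function(e) NULL)
    if (!is.null(t_r)) { n_ok <- n_ok + 1L; reps[[n_ok]] <- t_r }
  }
  if (n_ok == 0L) stop("no bootstrap replicate produced a defined tree")
  reps <- reps[seq_len(n_ok)]
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  tree$node.label <- 100 * counts / n_ok
  attr(tree, "n_replicates") <- n_replicates
  attr(tree, "n_successful") <- n_ok
  tree
}

#' Test whether a tree contains a given leaf bipartition
#'
#' @param tree `phylo` object.
#' @param group Character vector of tip labels forming one side of the
#'   split.
#' @return `TRUE` iff some internal edge separates `group` from the
#'   remaining tips.
#' @export
has_bipartition <- function(tree, group) {
  tips <- tree$tip.label
  target <- sort(match(group, tips))
  if (anyNA(target)) stop("group contains unknown tip labels")
  parts <- ape::prop.part(tree)
  comp <- sort(setdiff(seq_along(tips), target))
  any(vapply(parts, function(p)
    identical(sort(p), target) || identical(sort(p), comp), logical(1)))
}
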