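## qRT-PCR relative quantification against a single reference gene
## (2^-ddCt) and tissue-pattern summaries.

#' Relative expression by the delta-delta-Ct method
#'
#' Per (gene, sample): `dCt = mean(Ct_gene) - mean(Ct_reference)`,
#' `ddCt = dCt_sample - dCt_calibrator`, and the relative quantity
#' `RQ = efficiency^(-ddCt)` (efficiency 2 assumes perfect doubling per
#' cycle).  Replicate SDs are propagated as
#' `sqrt(sd_gene^2 + sd_reference^2)` on the dCt scale.
#'
#' @param ct data.frame of Ct records (`gene_id`, `sample`,
#'   `replicate`, `ct`), e.g. from [read_ct_table()].
#' @param reference_gene Reference (housekeeping) gene id, measured in
#'   every sample.
#' @param calibrator_sample Sample whose dCt anchors the scale; default
#'   the first sample in the table.
#' @param efficiency Amplification efficiency (default 2).
#' @return Object of class `expression_matrix`: list with `rq` (gene x
#'   sample matrix), `delta_ct`, `sd_delta_ct`, `reference_gene`,
#'   `calibrator_sample`.  The reference gene's RQ is 1 in every sample
#'   by construction.
#' @export
relative_expression <- function(ct, reference_gene,
                                calibrator_sample = NULL,
                                efficiency = 2) {
  stopifnot(all(c("gene_id", "sample", "replicate", "ct") %in% names(ct)))
  genes <- unique(ct$gene_id)
  samples <- unique(ct$sample)
  if (is.null(calibrator_sample)) calibrator_sample <- samples[1L]
  if (!reference_gene %in% genes)
    stop("reference gene '", reference_gene, "' not in the Ct table")
  if (!calibrator_sample %in% samples)
    stop("calibrator sample '", calibrator_sample, "' not in the Ct table")
  mean_ct <- sd_ct <- matrix(NA_real_, length(genes), length(samples),
                             dimnames = list(genes, samples))
  for (g in genes) for (s in samples) {
    v <- ct$ct[ct$gene_id == g & ct$sample == s]
    if (length(v) >= 1L) {
      mean_ct[g, s] <- mean(v)
      sd_ct[g, s] <- if (length(v) > 1L) stats::sd(v) else 0
    }
  }
  if (anyNA(mean_ct[reference_gene, ]))
    stop("reference gene not measured in sample(s): ",
         paste(samples[is.na(mean_ct[reference_gene, ])], collapse = ", "))
  if (anyNA(mean_ct[, calibrator_sample]))
    stop("calibrator sample missing for gene(s): ",
         paste(genes[is.na(mean_ct[, calibrator_sample])], collapse = ", "))
  dct <- sweep(mean_ct, 2L, mean_ct[reference_gene, ], `-`)
  sd_dct <- sqrt(sweep(sd_ct^2, 2L, sd_ct[reference_gene, ]^2, `+`))
  ddct <- sweep(dct, 1L, dct[, calibrator_sample], `-`)
  rq <- efficiency^(-ddct)
  structure(
    list(rq = rq, delta_ct = dct, sd_delta_ct = sd_dct,
         reference_gene = reference_gene,
         calibrator_sample = calibrator_sample,
         efficiency = efficiency),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Relative expression (", x$efficiency, "^-ddCt) of ",
      nrow(x$rq), " genes in ", ncol(x$rq), " samples\n",
      "reference: ", x$reference_gene, "; calibrator: ",
      x$calibrator_sample, "\n", sep = "")
  print(round(x$rq, 4), ...)
  invisible(x)
}

#' Sample of maximal expression per gene
#'
#' @param em An `expression_matrix`.
#' @param tol Relative tolerance for ties.
#' @return Named list: per gene, the character vector of samples
#'   attaining the maximal relative quantity (length > 1 on ties).
#' @export
tissue_maxima <- function(em, tol = 1e-9) {
  apply(em$rq, 1L, function(row) {
    mx <- max(row)
    colnames(em$rq)[row >= mx * (1 - tol)]
  }, simplify = FALSE)
}

#' Flag duplicate gene pairs with divergent expression patterns
#'
#' Two duplicates are pattern-divergent when their sets of
#' maximal-expression samples do not intersect — the signature read as
#' subfunctionalization after duplication.
#'
#' @param em An `expression_matrix`.
#' @param gene_a,gene_b Gene ids.
#' @return `TRUE` iff the maxima sets are disjoint.
#' @export
pattern_divergent <- function(em, gene_a, gene_b) {
  mx <- tissue_maxima(em)
  length(intersect(mx[[gene_a]], mx[[gene_b]])) == 0L
}

#' Row-standardized expression table for heatmap display
#'
#' Per-gene z-scores (mean 0, population SD 1); rows with zero variance
#' map to all zeros.  A display normalization only — relative
#' quantities remain the analytical output.
#'
#' @param em An `expression_matrix` (needs >= 2 samples).
#' @return Numeric matrix, same dimensions as `em$rq`.
#' @export
zscore_heatmap_table <- function(em) {
  if (ncol(em$rq) < 2L) stop("need at least 2 samples")
  t(apply(em$rq, 1L, function(row) {
    s <- sqrt(mean((row - mean(row))^2))
    if (is.na(s) || s == 0) rep(0, length(row))
    else (row - mean(row)) / s
  }))
}
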