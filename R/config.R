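#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline, defaulting to the values the
#' analyses are defined with: E-value cutoff 0.001 (strict `<`),
#' 100-kb flanking windows, blocks of three or more homolog pairs,
#' 150-bp/9-bp sliding windows, and the recent/ancient WGD Ks epochs.
#'
#' @param ... Named overrides of individual defaults.
#' @return Named list of configuration values.
#' @export
famsynt_config <- function(...) {
  cfg <- list(
    evalue_threshold = 0.001,
    domain_acc = "PF04873",
    window_bp = 100000L,
    min_pairs = 3L,
    kaks_window = 150L,
    kaks_step = 9L,
    kaks_min_codons = 10L,
    ks_recent = c(0.15, 0.3),
    ks_ancient = c(1.5, 1.8),
    bootstrap_replicates = 1000L,
    pcr_efficiency = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Read configuration overrides from an INI-style file
#'
#' Lines of the form `key = value` (comments with `#`); values are
#' parsed as numeric vectors where possible (comma-separated), else
#' kept as strings.  Keys must exist in [famsynt_config()].
#'
#' @param path Configuration file.
#' @return Full configuration list with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    overrides[[key]] <- if (anyNA(num)) val else num
  }
  do.call(famsynt_config, overrides)
}
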