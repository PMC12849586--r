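#' Pipeline run configuration
#'
#' Holds every tunable threshold of the pipeline with the published defaults:
#' 39-mers, the diagnostic ratio bands (A at ratio <= 1, low-confidence B in
#' (1, 1.1), high-confidence B at >= 1.1), the differential-expression
#' thresholds (|log2FC| >= 2, p <= 0.05) and the enrichment alpha (0.05).
#'
#' @param k k-mer size for contig classification (default 39; must be >= 11).
#' @param ratio_low lower bound of the B band (ratio <= ratio_low is A).
#' @param ratio_high high-confidence threshold (ratio >= ratio_high is
#'   high-confidence B).
#' @param max_ref_copy maximum assembly copy number of a diagnostic k-mer.
#' @param pseudocount added to summed +B/0B counts before forming the ratio.
#' @param min_diag_kmers contigs with fewer diagnostic k-mers are left
#'   unclassified.
#' @param lfc_threshold log2 fold-change threshold for DE calls.
#' @param p_threshold p-value threshold for DE calls.
#' @param enrich_alpha significance level for term enrichment.
#' @param seed master seed for any stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(k = 39L, ratio_low = 1.0, ratio_high = 1.1,
                       max_ref_copy = 1L, pseudocount = 1.0,
                       min_diag_kmers = 100L, lfc_threshold = 2.0,
                       p_threshold = 0.05, enrich_alpha = 0.05, seed = 1L) {
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11")
  if (k > 63L) stop("k must be <= 63 (2-bit packed storage)")
  if (!(ratio_low > 0 && ratio_low <= ratio_high))
    stop("need 0 < ratio_low <= ratio_high")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure(list(k = k, ratio_low = ratio_low, ratio_high = ratio_high,
                 max_ref_copy = as.integer(max_ref_copy),
                 pseudocount = pseudocount,
                 min_diag_kmers = as.integer(min_diag_kmers),
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 enrich_alpha = enrich_alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are an
#' error; values are coerced to the type of the corresponding [run_config()]
#' default. Keys absent from the file keep their defaults, and `overrides`
#' (e.g. parsed command-line flags) take precedence over the file.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return a `run_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: '", ln, "'")
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  defaults <- run_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- defaults
  for (nm in names(vals)) {
    v <- vals[[nm]]
    args[[nm]] <- if (is.integer(defaults[[nm]])) as.integer(v) else as.numeric(v)
  }
  do.call(run_config, unclass(args))
}
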