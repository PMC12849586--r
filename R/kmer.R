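#' Count canonical k-mers
#'
#' Builds an exact hash-table index of canonical k-mers (lexicographic minimum
#' of a k-mer and its reverse complement) over a set of DNA sequences. Windows
#' containing `N` are skipped; every other length-`k` window increments its
#' canonical form, so the total stored mass equals the number of valid
#' windows.
#'
#' @param sequences character vector of DNA sequences (a [contig_set()] or
#'   [read_set()]).
#' @param k k-mer size (11..63 for classification; smaller k is permitted for
#'   repeat scanning via the internal interface).
#' @param source label recorded on the index (`"reference"`,
#'   `"reads_plusB"`, `"reads_0B"`, ...).
#' @return a `kmer_index` object (external pointer to the C++ table, plus `k`,
#'   `mass` and `source`).
#' @export
count_kmers <- function(sequences, k, source = "reference") {
  k <- as.integer(k)
  if (k < 1L || k > 63L) stop("k must be in [1, 63]")
  assert_dna(toupper(as.character(sequences)), "sequence")
  if (length(sequences) && k > max(nchar(sequences)))
    warning("k exceeds the longest sequence; index is empty")
  ptr <- kt_build(toupper(as.character(sequences)), k)
  structure(list(ptr = ptr, k = k, mass = kt_mass(ptr),
                 n_distinct = kt_size(ptr), source = source),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index (k=%d, source=%s): %s distinct k-mers, mass %s\n",
              x$k, x$source, format(x$n_distinct, big.mark = ","),
              format(x$mass, big.mark = ",")))
  invisible(x)
}

#' Counts stored in a k-mer index
#'
#' Materializes the full table (small indexes only) or looks up specific
#' k-mers, canonicalizing them first.
#'
#' @param index a `kmer_index`.
#' @param kmers optional character vector of k-mers to look up; absent k-mers
#'   return 0.
#' @return named numeric vector of counts.
#' @export
kmer_counts <- function(index, kmers = NULL) {
  if (is.null(kmers)) {
    e <- kt_entries(index$ptr)
    return(setNames(e$count, e$kmer))
  }
  setNames(kt_lookup(index$ptr, toupper(kmers)), kmers)
}

#' Diagnostic (low-copy) k-mers of a contig
#'
#' A contig's canonical k-mers whose copy number in the whole-assembly index is
#' at most `max_ref_copy`. With the default of 1 this removes every k-mer
#' shared with any other locus (including a second occurrence within the same
#' contig), so the surviving set tracks the copy number of single loci and is
#' insensitive to repeat families.
#'
#' @param contig a single DNA sequence (character scalar).
#' @param reference_index `kmer_index` built from the full assembly; it must
#'   contain the contig (an error is raised otherwise).
#' @param max_ref_copy maximum assembly copy number (default 1).
#' @return character vector of diagnostic canonical k-mers, with attribute
#'   `n_diag`.
#' @export
find_diagnostic_kmers <- function(contig, reference_index, max_ref_copy = 1L) {
  stopifnot(length(contig) == 1L)
  km <- contig_diagnostic(toupper(contig), reference_index$ptr,
                          as.integer(max_ref_copy), TRUE)
  attr(km, "n_diag") <- length(km)
  km
}

#' Diagnostic-ratio score of one contig
#'
#' Sums +B and 0B read-set counts over a diagnostic k-mer set (each diagnostic
#' k-mer contributes once) and forms the depth-normalized ratio
#' \deqn{ratio = \frac{(c_+ + pc)/M_+}{(c_0 + pc)/M_0}}
#' where `M` is the total k-mer mass of the respective read set and `pc` the
#' pseudocount keeping the ratio finite when a B-specific contig has no 0B
#' coverage. When both libraries have equal mass this reduces to the plain
#' count ratio.
#'
#' @param diag_kmers character vector from [find_diagnostic_kmers()].
#' @param plusB_index,zeroB_index read-set `kmer_index`es (same k).
#' @return list with `c_plus`, `c_zero`, `ratio` (ratio is `NA` when the
#'   diagnostic set is empty).
#' @export
score_contig <- function(diag_kmers, plusB_index, zeroB_index, pseudocount = 1) {
  if (plusB_index$k != zeroB_index$k)
    stop("read indexes were built with different k")
  if (length(diag_kmers) == 0)
    return(list(c_plus = 0, c_zero = 0, ratio = NA_real_))
  c_plus <- sum(kt_lookup(plusB_index$ptr, diag_kmers))
  c_zero <- sum(kt_lookup(zeroB_index$ptr, diag_kmers))
  ratio <- ((c_plus + pseudocount) / plusB_index$mass) /
           ((c_zero + pseudocount) / zeroB_index$mass)
  list(c_plus = c_plus, c_zero = c_zero, ratio = ratio)
}

#' Classify a contig from its diagnostic ratio
#'
#' The published decision bands: too few diagnostic k-mers leaves a contig
#' `unclassified`; ratio <= `ratio_low` (1.0) is `A`; ratio strictly between
#' `ratio_low` and `ratio_high` is `B_low_confidence`; ratio >= `ratio_high`
#' (1.1) is `B_high_confidence` (a ratio of exactly 1.1 falls in both printed
#' clauses and the high-confidence rule takes precedence).
#'
#' @param ratio diagnostic ratio (may be `NA`).
#' @param n_diag diagnostic-set size.
#' @param config a [run_config()].
#' @return one of `"A"`, `"B_low_confidence"`, `"B_high_confidence"`,
#'   `"unclassified"`.
#' @export
classify_label <- function(ratio, n_diag, config = run_config()) {
  if (is.na(ratio) || n_diag < config$min_diag_kmers) return("unclassified")
  if (ratio <= config$ratio_low) return("A")
  if (ratio >= config$ratio_high) return("B_high_confidence")
  "B_low_confidence"
}

#' Welch two-sample t-test
#'
#' Plain Welch statistic with Welch-Satterthwaite degrees of freedom and
#' two-sided Student-t p-value. Zero variance in both groups yields the
#' limiting forms: equal means give `t = 0, p = 1`; unequal means give
#' `t = +/-Inf` and the smallest representable p.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_ttest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(d) * Inf, df = nx + ny - 2, p = .Machine$double.xmin))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = max(p, .Machine$double.xmin))
}

#' Classify every contig of an assembly from +B/0B read sets
#'
#' Builds the whole-assembly reference index and the two read-set indexes,
#' scores each contig over its diagnostic k-mers and applies the ratio bands.
#' Also runs the Welch t-test comparing depth-normalized per-contig +B vs 0B
#' counts over the contigs labelled B, and returns a scatter-ready table of
#' normalized counts.
#'
#' @param contigs a [contig_set()] (the assembly).
#' @param reads_plus,reads_zero [read_set()]s for the +B and 0B libraries.
#' @param config a [run_config()].
#' @return list with `classification` (one row per contig), `welch` (group
#'   test over B contigs, `NULL` if fewer than 2 B contigs), and `scatter`
#'   (per-contig normalized counts).
#' @export
classify_assembly <- function(contigs, reads_plus, reads_zero,
                              config = run_config()) {
  k <- config$k
  ref <- count_kmers(contigs, k, source = "reference")
  plus <- count_kmers(reads_plus, k, source = "reads_plusB")
  zero <- count_kmers(reads_zero, k, source = "reads_0B")

  n <- length(contigs)
  res <- data.frame(contig_id = names(contigs), length = nchar(contigs),
                    n_diag = integer(n), c_plus = numeric(n),
                    c_zero = numeric(n), ratio = NA_real_,
                    label = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- contig_diag_score(contigs[[i]], ref$ptr, plus$ptr, zero$ptr,
                           config$max_ref_copy, TRUE)
    res$n_diag[i] <- as.integer(s[["n_diag"]])
    res$c_plus[i] <- s[["c_plus"]]
    res$c_zero[i] <- s[["c_zero"]]
    res$ratio[i] <- if (s[["n_diag"]] > 0)
      ((s[["c_plus"]] + config$pseudocount) / plus$mass) /
      ((s[["c_zero"]] + config$pseudocount) / zero$mass) else NA_real_
    res$label[i] <- classify_label(res$ratio[i], res$n_diag[i], config)
  }
  rownames(res) <- NULL

  scatter <- data.frame(contig_id = res$contig_id,
                        plus_norm = res$c_plus / plus$mass,
                        zero_norm = res$c_zero / zero$mass,
                        stringsAsFactors = FALSE)

  isB <- res$label %in% c("B_low_confidence", "B_high_confidence")
  welch <- if (sum(isB) >= 2)
    welch_ttest(scatter$plus_norm[isB], scatter$zero_norm[isB]) else NULL

  list(classification = res, welch = welch, scatter = scatter,
       mass_plus = plus$mass, mass_zero = zero$mass)
}

#' Expression support for low-confidence B contigs
#'
#' A `B_low_confidence` contig is corroborated by RNA-seq when it carries at
#' least one gene whose size-factor-normalized mean count is at most
#' `tau_zero` in every 0B group and at least `tau_plus` in at least one +B
#' group, i.e. a gene expressed exclusively with the B chromosome present.
#' Contigs without annotated genes are flagged `not_applicable`.
#'
#' @param classification classification table from [classify_assembly()].
#' @param cm a [count_matrix()].
#' @param annotation a [gene_annotation()].
#' @param tau_zero,tau_plus normalized-count thresholds (defaults 1 and 5).
#' @return the classification table with an added `rnaseq_support` column
#'   (`supported` / `not_supported` / `not_applicable`).
#' @export
rnaseq_support <- function(classification, cm, annotation,
                           tau_zero = 1, tau_plus = 5) {
  sf <- size_factors_median_ratio(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  grp <- interaction(cm$samples$stage, cm$samples$b_status, drop = TRUE)
  gmeans <- t(apply(norm, 1, function(v) tapply(v, grp, mean)))
  is_plus <- grepl("\\+B$", colnames(gmeans))
  exclusive <- rownames(gmeans)[
    apply(gmeans[, !is_plus, drop = FALSE] <= tau_zero, 1, all) &
    apply(gmeans[, is_plus, drop = FALSE] >= tau_plus, 1, any)]

  support <- vapply(seq_len(nrow(classification)), function(i) {
    genes <- annotation$gene_id[annotation$contig_id ==
                                  classification$contig_id[i]]
    if (!length(genes)) return("not_applicable")
    if (any(genes %in% exclusive)) "supported" else "not_supported"
  }, character(1))
  classification$rnaseq_support <- support
  classification
}
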