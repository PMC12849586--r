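#' Median-of-ratios size factors
#'
#' The classic normalization estimator: for each sample `j`,
#' `s_j = median_g c_gj / GM_g` over genes whose geometric mean `GM_g`
#' across all samples is positive (i.e. genes with no zero count anywhere).
#'
#' @param cm a [count_matrix()] (or plain counts matrix).
#' @return named numeric vector of positive size factors.
#' @export
size_factors_median_ratio <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  logc <- log(counts)
  glog <- rowMeans(logc)                 # -Inf for any gene with a zero
  eligible <- is.finite(glog)
  if (!any(eligible))
    stop("no gene has positive counts in every sample; ",
         "add a pseudocount upstream or filter samples")
  sf <- apply(counts[eligible, , drop = FALSE], 2, function(col)
    median(exp(log(col) - glog[eligible])))
  if (any(sf <= 0)) stop("non-positive size factor estimated")
  sf
}

#' Per-stage two-group differential expression
#'
#' A fully specified stand-in for a negative-binomial package fit: counts are
#' normalized by median-of-ratios size factors (computed within the
#' contrast), the fold change is
#' `log2((mean_{+B} n~ + 1) / (mean_{0B} n~ + 1))` with a pseudocount of 1 so
#' B-located genes with legitimate zero 0B expression stay finite, and the
#' p-value is a two-sided Welch t-test on `log2(n~ + 1)` between the +B and
#' 0B groups (0B is the base group). Calls use the published thresholds:
#' `up` iff `log2fc >= lfc_threshold` and `p <= p_threshold`; `down`
#' symmetrically. Raw p-values are thresholded as printed;
#' `adjust = "BH"` applies Benjamini-Hochberg first.
#'
#' @param cm a [count_matrix()] of raw counts.
#' @param stage the stage to contrast (`"early"`, `"mid"`, `"late"`, `"lcm"`).
#' @param config a [run_config()] (thresholds).
#' @param adjust `"none"` (default, as printed) or `"BH"`.
#' @return data.frame: `gene_id`, `base_mean`, `log2fc`, `p`, `call`.
#' @export
de_test <- function(cm, stage, config = run_config(), adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  sel <- cm$samples$stage == stage
  if (!any(sel)) stop("no samples for stage '", stage, "'")
  sub <- cm$counts[, sel, drop = FALSE]
  meta <- cm$samples[sel, , drop = FALSE]
  for (g in c("0B", "+B"))
    if (sum(meta$b_status == g) < 2)
      stop("group ", g, " has fewer than 2 replicates in stage '", stage, "'")
  sf <- size_factors_median_ratio(sub)
  norm <- sweep(sub, 2, sf, "/")
  lognorm <- log2(norm + 1)
  plus <- meta$b_status == "+B"

  mp <- rowMeans(norm[, plus, drop = FALSE])
  mz <- rowMeans(norm[, !plus, drop = FALSE])
  log2fc <- log2((mp + 1) / (mz + 1))
  p <- vapply(seq_len(nrow(sub)), function(i)
    welch_ttest(lognorm[i, plus], lognorm[i, !plus])$p, numeric(1))
  p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  call <- rep("ns", length(p))
  call[log2fc >= config$lfc_threshold & p_eff <= config$p_threshold] <- "up"
  call[log2fc <= -config$lfc_threshold & p_eff <= config$p_threshold] <- "down"
  data.frame(gene_id = rownames(sub), base_mean = (mp + mz) / 2,
             log2fc = log2fc, p = p_eff, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Restrict up-regulated genes to B-located genes
#'
#' @param up_genes character vector of up-called gene ids (order preserved).
#' @param annotation a [gene_annotation()].
#' @param b_contig_ids contig ids classified as B.
#' @return the subset of `up_genes` located on B contigs, in stable order.
#'   Genes absent from the annotation are dropped with a warning.
#' @export
match_to_b_contigs <- function(up_genes, annotation, b_contig_ids) {
  unknown <- setdiff(up_genes, annotation$gene_id)
  if (length(unknown))
    warning("unannotated gene(s) excluded: ", paste(unknown, collapse = ", "))
  known <- up_genes[up_genes %in% annotation$gene_id]
  ctg <- annotation$contig_id[match(known, annotation$gene_id)]
  known[ctg %in% b_contig_ids]
}
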