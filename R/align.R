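#' Protein alignment scoring scheme
#'
#' Defaults follow the cited global-alignment tool's protein settings:
#' BLOSUM62 (taken from Biostrings), gap open 10, gap extend 0.5, end gaps
#' free. A gap run of length L costs `gap_open + (L - 1) * gap_extend`
#' unless it touches either end of the alignment, in which case it is free.
#'
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix (symmetric, residue dimnames); default
#'   BLOSUM62.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(gap_open = 10, gap_extend = 0.5, matrix = NULL) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps_penalized = FALSE),
            class = "scoring_scheme")
}

#' Global pairwise alignment with affine gaps and free end gaps
#'
#' Three-state (Gotoh) dynamic programming. Tie-breaking during traceback is
#' deterministic: diagonal is preferred over up (gap in the second sequence)
#' over left. Identity is the percentage of identical columns over the full
#' alignment length, which is what makes terminal truncations depress the
#' identity of a pair.
#'
#' @param seqA,seqB amino-acid sequences (single strings; residues must
#'   appear in the scoring matrix).
#' @param scheme a [scoring_scheme()].
#' @return a `pairwise_alignment`: `aligned_A`, `aligned_B`, `score`,
#'   `identity_pct`, `gap_columns`, `alignment_length`.
#' @export
global_align_affine <- function(seqA, seqB, scheme = scoring_scheme()) {
  stopifnot(length(seqA) == 1, length(seqB) == 1)
  alpha <- paste(rownames(scheme$matrix), collapse = "")
  res <- gotoh_align(seqA, seqB, scheme$matrix, alpha,
                     scheme$gap_open, scheme$gap_extend)
  a <- strsplit(res$aligned_A, "", fixed = TRUE)[[1]]
  b <- strsplit(res$aligned_B, "", fixed = TRUE)[[1]]
  if (any(a == "-" & b == "-")) stop("internal error: gap-gap column")
  ident <- sum(a == b & a != "-")
  structure(list(aligned_A = res$aligned_A, aligned_B = res$aligned_B,
                 score = res$score,
                 identity_pct = 100 * ident / length(a),
                 gap_columns = sum(a == "-" | b == "-"),
                 alignment_length = length(a)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: length %d, score %.1f, identity %.2f%%\n",
              x$alignment_length, x$score, x$identity_pct))
  invisible(x)
}

#' List polymorphisms of a pairwise alignment
#'
#' One record per mismatch column (substitution, labelled
#' `<aa_A><pos_A><aa_B>` with `pos_A` counting non-gap A columns) and per
#' maximal gap run (insertion = gap in A, deletion = gap in B). A gap run in
#' the B variant touching either alignment end and longer than `trunc_min`
#' is reported as a `terminal_truncation`.
#'
#' @param aln a `pairwise_alignment`.
#' @param trunc_min minimum terminal B-gap run length called a truncation.
#' @return data.frame: `pos_A`, `aa_A`, `aa_B`, `kind`, `length`, `label`.
#' @export
list_polymorphisms <- function(aln, trunc_min = 10) {
  a <- strsplit(aln$aligned_A, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned_B, "", fixed = TRUE)[[1]]
  posA <- cumsum(a != "-")
  rows <- list()
  # substitutions
  subs <- which(a != b & a != "-" & b != "-")
  for (i in subs)
    rows[[length(rows) + 1L]] <- data.frame(
      pos_A = posA[i], aa_A = a[i], aa_B = b[i], kind = "substitution",
      length = 1L, label = paste0(a[i], posA[i], b[i]),
      stringsAsFactors = FALSE)
  # maximal gap runs
  gap_runs <- function(isgap) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values],
               len = r$lengths[r$values])
  }
  for (run in split(gap_runs(b == "-"), seq_len(sum(rle(b == "-")$values)))) {
    terminal <- run$start == 1L || run$end == length(b)
    kind <- if (terminal && run$len > trunc_min) "terminal_truncation"
            else "deletion"
    rows[[length(rows) + 1L]] <- data.frame(
      pos_A = posA[run$start], aa_A = NA_character_, aa_B = "-", kind = kind,
      length = run$len,
      label = sprintf("%s%d:%d",
                      if (kind == "terminal_truncation") "trunc" else "del",
                      posA[run$start], run$len),
      stringsAsFactors = FALSE)
  }
  for (run in split(gap_runs(a == "-"), seq_len(sum(rle(a == "-")$values)))) {
    rows[[length(rows) + 1L]] <- data.frame(
      pos_A = if (run$start == 1L) 0L else posA[run$start], aa_A = "-",
      aa_B = NA_character_, kind = "insertion", length = run$len,
      label = sprintf("ins%d:%d", posA[run$start], run$len),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pos_A = integer(0), aa_A = character(0),
                      aa_B = character(0), kind = character(0),
                      length = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$pos_A, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare A/B protein variant pairs
#'
#' Aligns each B copy of each gene against the gene's A variant and tabulates
#' identity, substitution count and truncation status.
#'
#' @param variants list of `list(gene, copy, seqA, seqB)` entries (or the
#'   `pairs` element of [simulate_protein_pairs()], where `copy` defaults to
#'   1), or a FASTA file read with [read_protein_variants()].
#' @param scheme a [scoring_scheme()].
#' @param trunc_min passed to [list_polymorphisms()].
#' @return data.frame: `gene`, `copy`, `identity_pct`, `n_substitutions`,
#'   `truncated`, `labels`, sorted by gene then copy. Pairs without an A
#'   variant are flagged (`identity_pct` = NA).
#' @export
compare_variant_pairs <- function(variants, scheme = scoring_scheme(),
                                  trunc_min = 10) {
  rows <- lapply(variants, function(v) {
    copy <- v$copy %||% 1L
    if (is.null(v$seqA) || !nzchar(v$seqA %||% ""))
      return(data.frame(gene = v$gene, copy = copy, identity_pct = NA_real_,
                        n_substitutions = NA_integer_, truncated = NA,
                        labels = "missing_A_variant", stringsAsFactors = FALSE))
    aln <- global_align_affine(v$seqA, v$seqB, scheme)
    poly <- list_polymorphisms(aln, trunc_min)
    subs <- poly[poly$kind == "substitution", , drop = FALSE]
    data.frame(gene = v$gene, copy = copy, identity_pct = aln$identity_pct,
               n_substitutions = nrow(subs),
               truncated = any(poly$kind == "terminal_truncation"),
               labels = paste(subs$label, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$copy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein variants from FASTA with `<gene>|<A or B>|<copy>` headers
#'
#' @param path protein FASTA.
#' @return a list of `list(gene, copy, seqA, seqB)` suitable for
#'   [compare_variant_pairs()]; B copies without an A variant get
#'   `seqA = NULL`.
#' @export
read_protein_variants <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  parts <- strsplit(sub("\\s.*$", "", names(x)), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("header must be <gene>|<A|B>|<copy>: ", names(x)[bad][1])
  tab <- data.frame(gene = vapply(parts, `[`, "", 1),
                    variant = vapply(parts, `[`, "", 2),
                    copy = as.integer(vapply(parts, `[`, "", 3)),
                    seq = as.character(x), stringsAsFactors = FALSE)
  if (!all(tab$variant %in% c("A", "B")))
    stop("variant field must be 'A' or 'B'")
  out <- list()
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, , drop = FALSE]
    aseq <- sub$seq[sub$variant == "A"][1]
    for (i in which(sub$variant == "B"))
      out[[length(out) + 1L]] <- list(gene = g, copy = sub$copy[i],
                                      seqA = if (is.na(aseq)) NULL else aseq,
                                      seqB = sub$seq[i])
  }
  out
}
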