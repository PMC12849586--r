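# Independent brute-force oracles. These deliberately share no code with the
# package internals they check (string windows vs 2-bit rolling hash; move
# enumeration vs Gotoh DP; draw enumeration vs phyper).

# -- canonical k-mer counting by window enumeration ---------------------------
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_count_kmers <- function(seqs, k) {
  tab <- list()
  for (s in toupper(seqs)) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      canon <- min(w, oracle_revcomp(w))
      tab[[canon]] <- (tab[[canon]] %||% 0) + 1
    }
  }
  unlist(tab) %||% setNames(numeric(0), character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna_str <- function(len, with_n = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# -- affine-gap global alignment score by exhaustive move enumeration ---------
# Gap cost: gap_open for the first column of a run, gap_extend for each
# further column; the first and last run of the alignment are free when they
# are gap runs (free end gaps).
oracle_align_score <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  S <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  m <- length(A); n <- length(B)
  best <- -Inf
  score_moves <- function(mv) {
    r <- rle(mv)
    ai <- cumsum(mv != 3L); bj <- cumsum(mv != 2L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sc <- 0
    for (t in seq_along(r$values)) {
      if (r$values[t] == 1L) {
        cols <- starts[t]:ends[t]
        sc <- sc + sum(S[cbind(A[ai[cols]], B[bj[cols]])])
      } else if (t != 1L && t != length(r$values)) {
        sc <- sc - (go + (r$lengths[t] - 1) * ge)
      }
    }
    sc
  }
  rec <- function(i, j, mv) {
    if (i == m && j == n) {
      best <<- max(best, score_moves(mv))
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1L, j + 1L, c(mv, 1L))
    if (i < m) rec(i + 1L, j, c(mv, 2L))
    if (j < n) rec(i, j + 1L, c(mv, 3L))
  }
  rec(0L, 0L, integer(0))
  best
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# -- hypergeometric upper tail by enumerating all draws -----------------------
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# -- small expression worlds --------------------------------------------------
flat_annotation <- function(n, contig = "A_01", prefix = "g") {
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  gene_annotation(ids, rep(contig, n), 1000L * seq_len(n),
                  1000L * seq_len(n) + 299L)
}

# Venn-region tallies by direct membership enumeration.
oracle_overlap_counts <- function(sets) {
  genes <- unique(unlist(sets))
  pats <- vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&"), character(1))
  table(pats)
}
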