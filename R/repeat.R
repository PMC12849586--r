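#' Canonical k-mer set of a tandem monomer, phase-free
#'
#' Tandem arrays start at an arbitrary rotation of the monomer, so the
#' monomer is doubled and the first `2*monomer_len - k + 1` windows are
#' collected; the resulting canonical set is invariant under cyclic rotation
#' of the input.
#'
#' @param monomer DNA consensus sequence of the repeat monomer.
#' @param k scan k-mer size (default 17; must not exceed the monomer length).
#' @param neighbors also include all 1-mismatch neighbours of each k-mer
#'   (tolerates diverged monomer copies; off by default).
#' @return character vector of canonical k-mers.
#' @export
rotation_kmer_set <- function(monomer, k = 17L, neighbors = FALSE) {
  monomer <- toupper(monomer)
  assert_dna(monomer, "monomer", allow_n = FALSE)
  if (k > nchar(monomer))
    stop("k (", k, ") exceeds the monomer length (", nchar(monomer), ")")
  doubled <- paste0(monomer, monomer)
  win <- seq_len(2L * nchar(monomer) - k + 1L)
  kms <- unique(seq_canonical_windows(doubled, as.integer(k))[win])
  kms <- kms[!is.na(kms)]
  if (neighbors) {
    bases <- c("A", "C", "G", "T")
    nb <- unlist(lapply(kms, function(km) {
      ch <- strsplit(km, "", fixed = TRUE)[[1]]
      unlist(lapply(seq_len(k), function(i) {
        vapply(setdiff(bases, ch[i]), function(b) {
          x <- ch; x[i] <- b; paste(x, collapse = "")
        }, character(1))
      }))
    }))
    # canonicalize the neighbours too
    nb <- unique(vapply(nb, function(s) min(s, revcomp(s)), character(1)))
    kms <- unique(c(kms, nb))
  }
  sort(kms)
}

#' Annotate tandem-repeat arrays on a contig
#'
#' Every contig position covered by a window whose canonical k-mer belongs to
#' the repeat's rotation set is marked; maximal marked runs separated by at
#' most `gap_tol` unmarked bases are merged into hits.
#'
#' @param contig a single DNA sequence.
#' @param kmer_set character vector from [rotation_kmer_set()].
#' @param k the k used to build `kmer_set`.
#' @param gap_tol maximum unmarked gap merged into a hit (default `2 * k`).
#' @return list with `hits` (data.frame `start`, `end`, `covered_bp`, 1-based
#'   inclusive) and `coverage` (marked bases / contig length).
#' @export
annotate_repeat <- function(contig, kmer_set, k = 17L, gap_tol = 2L * k) {
  contig <- toupper(contig)
  L <- nchar(contig)
  if (L < k) stop("contig shorter than k")
  wins <- seq_canonical_windows(contig, as.integer(k))
  hit_win <- which(!is.na(wins) & wins %in% kmer_set)
  delta <- integer(L + 1L)
  if (length(hit_win)) {
    add <- tabulate(hit_win, nbins = L + 1L)
    rem <- tabulate(pmin(hit_win + k, L + 1L), nbins = L + 1L)
    delta <- add - rem
  }
  covered <- cumsum(delta)[seq_len(L)] > 0L
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hs <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(hs) > 1) {
    merged <- hs[1, , drop = FALSE]
    for (i in 2:nrow(hs)) {
      if (hs$start[i] - merged$end[nrow(merged)] - 1L <= gap_tol)
        merged$end[nrow(merged)] <- hs$end[i]
      else merged <- rbind(merged, hs[i, ])
    }
    hs <- merged
  }
  cov_in <- function(s, e) sum(covered[s:e])
  hs$covered_bp <- if (nrow(hs)) mapply(cov_in, hs$start, hs$end) else integer(0)
  rownames(hs) <- NULL
  list(hits = hs, coverage = sum(covered) / L)
}

#' Scan an assembly for two repeat families and report co-occurrence
#'
#' @param contigs a [contig_set()].
#' @param monomers named character vector of exactly two monomer consensus
#'   sequences.
#' @param k scan k-mer size (default 17).
#' @param gap_tol run-merging tolerance (default `2 * k`).
#' @param min_span minimum total covered bp per repeat for a contig to count
#'   as carrying it (default: the larger monomer length).
#' @param neighbors passed to [rotation_kmer_set()].
#' @return list with `hits` (per contig and repeat: intervals), `profiles`
#'   (per contig and repeat: total covered bp, coverage fraction) and
#'   `cooccurrence` (contigs carrying both repeats, with both repeats'
#'   intervals for co-localization inspection).
#' @export
scan_repeats <- function(contigs, monomers, k = 17L, gap_tol = 2L * k,
                         min_span = NULL, neighbors = FALSE) {
  if (length(monomers) != 2L || is.null(names(monomers)))
    stop("monomers must be a named vector of exactly two sequences")
  if (is.null(min_span)) min_span <- max(nchar(monomers))
  sets <- lapply(monomers, rotation_kmer_set, k = k, neighbors = neighbors)
  hits <- list(); prof <- list()
  for (cid in names(contigs)) {
    for (rn in names(monomers)) {
      ann <- annotate_repeat(contigs[[cid]], sets[[rn]], k = k,
                             gap_tol = gap_tol)
      if (nrow(ann$hits))
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = cid, repeat_name = rn, ann$hits,
          stringsAsFactors = FALSE)
      prof[[length(prof) + 1L]] <- data.frame(
        contig_id = cid, repeat_name = rn,
        covered_bp = sum(ann$hits$covered_bp), coverage = ann$coverage,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig_id = character(0), repeat_name = character(0),
               start = integer(0), end = integer(0), covered_bp = integer(0))
  prof <- do.call(rbind, prof)
  rownames(hits) <- rownames(prof) <- NULL
  co <- cooccurrence_report(prof, hits, min_span)
  list(hits = hits, profiles = prof, cooccurrence = co)
}

#' Contigs where two repeat families co-occur
#'
#' A contig is reported when both repeats cover at least `min_span` bp on it;
#' the report carries both repeats' intervals so co-localization can be
#' inspected. Symmetric in the two repeats.
#'
#' @param profiles per-contig/repeat covered-bp table (from
#'   [scan_repeats()]).
#' @param hits per-contig/repeat interval table.
#' @param min_span minimum covered bp per repeat.
#' @return list with `contigs` (character vector) and `intervals`
#'   (subset of `hits` on those contigs).
#' @export
cooccurrence_report <- function(profiles, hits, min_span) {
  reps <- unique(profiles$repeat_name)
  ok <- lapply(reps, function(rn)
    profiles$contig_id[profiles$repeat_name == rn &
                         profiles$covered_bp >= min_span])
  contigs <- sort(Reduce(intersect, ok))
  list(contigs = contigs,
       intervals = hits[hits$contig_id %in% contigs, , drop = FALSE])
}
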