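#' Genome simulation configuration
#'
#' The stated world the generator emulates: a small standard (A) complement
#' plus a B chromosome that is a mosaic of diverged multi-A-origin segments
#' and novel B-specific sequence, with lower gene density on B (~1.3% vs
#' ~3.9% coding), higher repeat content (60% vs 55%), a 137 bp centromeric
#' satellite shared by A and B, and a 166 bp B-specific satellite that
#' co-occurs with it.
#'
#' @param n_A,A_len number and length of A contigs (8 x 60 kb).
#' @param n_B,B_len number and length of B contigs (4 x 40 kb).
#' @param segments_per_B A-derived segments per B contig, each copied from a
#'   distinct A contig.
#' @param divergence per-base substitution probability applied to A-derived B
#'   segments (default 0.03; the magnitude of A/B divergence is not published
#'   and this is a free parameter).
#' @param b_specific_fraction fraction of each B contig that is novel sequence
#'   including the B-specific satellite arrays.
#' @param gene_density_A,gene_density_B target coding fractions.
#' @param repeat_fraction_A,repeat_fraction_B target repeat fractions
#'   (dispersed families plus satellite arrays).
#' @param sat_A_monomer_len,sat_B_monomer_len satellite monomer lengths.
#' @param gene_len length of each simulated gene (bp).
#' @param sat_divergence per-base substitution probability applied to interior
#'   satellite monomer copies (terminal copies are exact so planted array
#'   boundaries are well-defined ground truth).
#' @return a `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_A = 8L, A_len = 60000L, n_B = 4L,
                              B_len = 40000L, segments_per_B = 4L,
                              divergence = 0.03, b_specific_fraction = 0.3,
                              gene_density_A = 0.039, gene_density_B = 0.013,
                              repeat_fraction_A = 0.55,
                              repeat_fraction_B = 0.60,
                              sat_A_monomer_len = 137L,
                              sat_B_monomer_len = 166L,
                              gene_len = 300L, sat_divergence = 0.01) {
  stopifnot(segments_per_B <= n_A,
            b_specific_fraction >= 0, b_specific_fraction <= 1,
            divergence >= 0, divergence <= 1)
  if (gene_density_A + repeat_fraction_A > 1 ||
      gene_density_B + repeat_fraction_B + b_specific_fraction > 1.3)
    stop("infeasible packing: densities sum too close to 1")
  as.list(environment()) |> structure(class = "genome_sim_config")
}

# Dispersed repeat-family copies (2% per-copy divergence) summing to at most
# `budget` bases: families are drawn at random among those that still fit.
draw_repeat_copies <- function(fams, budget) {
  out <- list()
  used <- 0
  repeat {
    fit <- fams[nchar(fams) <= budget - used]
    if (!length(fit)) break
    fam <- sample(names(fit), 1)
    cp <- mutate_dna(fit[[fam]], 0.02)
    out[[length(out) + 1L]] <- cp
    used <- used + nchar(cp)
  }
  out
}

# One satellite tandem array: n_copies of the monomer starting at a random
# rotation; interior copies diverged at sat_divergence, terminal copies exact.
make_sat_array <- function(monomer, n_copies, sat_divergence) {
  rot <- sample.int(nchar(monomer), 1)
  mono <- paste0(substring(monomer, rot), substring(monomer, 1, rot - 1))
  copies <- character(n_copies)
  for (i in seq_len(n_copies)) {
    copies[i] <- if (i == 1 || i == n_copies) mono
                 else mutate_dna(mono, sat_divergence)
  }
  paste(copies, collapse = "")
}

#' Simulate an A genome plus B chromosome with ground truth
#'
#' A contigs are built from interspersed random sequence, copies of three
#' dispersed repeat families (LTR-like 5 kb, DNA-transposon-like 3 kb, short
#' 300 bp family; 2% per-copy divergence), genes, and one shared-satellite
#' tandem array each. Each B contig is a mosaic of diverged segments copied
#' from distinct A contigs, novel B-specific sequence containing a region
#' where the shared and the B-specific satellite co-occur, and B genes. In
#' the degenerate limit `divergence = 0, b_specific_fraction = 0` a B contig
#' is a pure mosaic of A segments (genes are annotated on the segments), so
#' every B k-mer also occurs in A.
#'
#' @param config a [genome_sim_config()].
#' @param seed integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return list with `contigs` ([contig_set()], A then B), `annotation`
#'   ([gene_annotation()]), `truth` (list: `b_contigs`, `b_genes`,
#'   `cooccurrence_contigs`, satellite consensi and per-contig planted array
#'   intervals `sat_arrays`), and `repeats` (named consensus sequences).
#' @export
simulate_genome <- function(config = genome_sim_config(), seed = 1L) {
  with_seed(derive_seed(seed, "genome"), {
    sat_A <- random_dna(1, config$sat_A_monomer_len)
    sat_B <- random_dna(1, config$sat_B_monomer_len)
    fams <- list(LTR_like = random_dna(1, 5000),
                 DNA_transposon_like = random_dna(1, 3000),
                 short_interspersed = random_dna(1, 300))

    genes <- list()
    sat_arrays <- list()
    gene_counter <- 0L

    build_contig <- function(blocks, contig_id) {
      # blocks: list of list(type, seq, gene=TRUE/FALSE, sat=name or NA)
      ord <- sample(length(blocks))
      blocks <- blocks[ord]
      pos <- 1L
      seqs <- character(length(blocks))
      for (i in seq_along(blocks)) {
        b <- blocks[[i]]
        len <- nchar(b$seq)
        if (isTRUE(b$gene)) {
          gene_counter <<- gene_counter + 1L
          genes[[length(genes) + 1L]] <<- data.frame(
            gene_id = sprintf("g%05d", gene_counter), contig_id = contig_id,
            start = pos, end = pos + len - 1L,
            strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
        }
        if (!is.null(b$sat)) {
          sat_arrays[[length(sat_arrays) + 1L]] <<- data.frame(
            contig_id = contig_id, repeat_name = b$sat,
            start = pos, end = pos + len - 1L, stringsAsFactors = FALSE)
        }
        seqs[i] <- b$seq
        pos <- pos + len
      }
      paste(seqs, collapse = "")
    }

    fill_blocks <- function(total_len, blocks) {
      used <- sum(vapply(blocks, function(b) nchar(b$seq), numeric(1)))
      rem <- total_len - used
      if (rem < 0) stop("infeasible packing: blocks exceed contig length")
      # split remainder into filler chunks so block order can vary
      n_chunks <- max(1L, length(blocks))
      cuts <- sort(sample.int(rem + 1L, n_chunks - 1L, replace = TRUE) - 1L)
      sizes <- diff(c(0L, cuts, rem))
      for (s in sizes[sizes > 0]) {
        blocks[[length(blocks) + 1L]] <- list(seq = random_dna(1, s))
      }
      blocks
    }

    contigs <- character(0)

    # ---- A contigs ----
    for (i in seq_len(config$n_A)) {
      id <- sprintf("A_%02d", i)
      L <- config$A_len
      blocks <- list()
      # shared satellite array (~3% of the contig, part of the repeat budget)
      n_cop <- max(5L, round(0.03 * L / config$sat_A_monomer_len))
      arr <- make_sat_array(sat_A, n_cop, config$sat_divergence)
      blocks[[length(blocks) + 1L]] <- list(seq = arr, sat = "sat_A")
      rep_target <- config$repeat_fraction_A * L - nchar(arr)
      for (cp in draw_repeat_copies(fams, rep_target))
        blocks[[length(blocks) + 1L]] <- list(seq = cp)
      n_genes <- round(config$gene_density_A * L / config$gene_len)
      for (g in seq_len(n_genes))
        blocks[[length(blocks) + 1L]] <- list(seq = random_dna(1, config$gene_len),
                                              gene = TRUE)
      blocks <- fill_blocks(L, blocks)
      contigs[id] <- build_contig(blocks, id)
    }

    # ---- B contigs ----
    a_ids <- names(contigs)
    for (i in seq_len(config$n_B)) {
      id <- sprintf("B_%02d", i)
      L <- config$B_len
      degenerate <- config$b_specific_fraction == 0 && config$divergence == 0
      n_genes <- round(config$gene_density_B * L / config$gene_len)
      seg_sources <- sample(a_ids, config$segments_per_B)
      gene_budget <- if (degenerate) 0L else n_genes * config$gene_len
      novel_budget <- round(config$b_specific_fraction * L)
      seg_total <- L - novel_budget - gene_budget
      seg_len <- floor(seg_total / config$segments_per_B)

      blocks <- list()
      for (src in seg_sources) {
        src_seq <- contigs[[src]]
        st <- sample.int(nchar(src_seq) - seg_len + 1L, 1)
        seg <- substring(src_seq, st, st + seg_len - 1L)
        blocks[[length(blocks) + 1L]] <- list(seq = mutate_dna(seg, config$divergence))
      }
      if (!degenerate) {
        # co-occurring satellite region: shared + B-specific arrays, adjacent.
        # Both arrays plus the extra dispersed repeats live inside the novel
        # (B-specific) budget.
        n_a <- max(5L, round(0.10 * novel_budget / config$sat_A_monomer_len))
        n_b <- max(5L, round(0.17 * novel_budget / config$sat_B_monomer_len))
        arr_a <- make_sat_array(sat_A, n_a, config$sat_divergence)
        arr_b <- make_sat_array(sat_B, n_b, config$sat_divergence)
        # keep the two arrays glued together as one block so both land in one
        # region; record their sub-intervals
        glued <- paste0(arr_a, arr_b)
        if (nchar(glued) > novel_budget)
          stop("infeasible packing: b_specific_fraction too small for the ",
               "satellite co-occurrence region")
        blocks[[length(blocks) + 1L]] <- list(seq = glued, sat = "sat_AB",
                                              sat_a_len = nchar(arr_a))
        for (g in seq_len(n_genes))
          blocks[[length(blocks) + 1L]] <- list(seq = random_dna(1, config$gene_len),
                                                gene = TRUE)
        # B repeat surplus: extra dispersed-family copies beyond the A level,
        # capped by what is left of the novel budget
        extra_rep <- min((config$repeat_fraction_B - config$repeat_fraction_A) * L,
                         novel_budget - nchar(glued))
        for (cp in draw_repeat_copies(fams, extra_rep))
          blocks[[length(blocks) + 1L]] <- list(seq = cp)
      }
      blocks <- fill_blocks(L, blocks)
      contigs[id] <- build_contig(blocks, id)

      if (degenerate && n_genes > 0) {
        # annotate genes on intervals of the copied segments
        for (g in seq_len(n_genes)) {
          gene_counter <- gene_counter + 1L
          st <- sample.int(L - config$gene_len, 1)
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = sprintf("g%05d", gene_counter), contig_id = id,
            start = st, end = st + config$gene_len - 1L, strand = "+",
            stringsAsFactors = FALSE)
        }
      }
    }

    gtab <- do.call(rbind, genes)
    ann <- gene_annotation(gtab$gene_id, gtab$contig_id, gtab$start,
                           gtab$end, gtab$strand)
    sats <- do.call(rbind, sat_arrays)
    # expand glued co-occurrence blocks into their two component intervals
    co <- sats$repeat_name == "sat_AB"
    if (any(co)) {
      glued_rows <- sats[co, , drop = FALSE]
      sats <- sats[!co, , drop = FALSE]
      # sat_A part length recorded implicitly: recompute from monomer counts
      nb <- round(config$b_specific_fraction * config$B_len)
      n_a_len <- max(5L, round(0.10 * nb / config$sat_A_monomer_len)) *
        config$sat_A_monomer_len
      a_part <- transform(glued_rows, repeat_name = "sat_A",
                          end = start + n_a_len - 1L)
      b_part <- transform(glued_rows, repeat_name = "sat_B",
                          start = start + n_a_len)
      sats <- rbind(sats, a_part, b_part)
    }
    rownames(sats) <- NULL

    b_ids <- grep("^B_", names(contigs), value = TRUE)
    truth <- list(
      b_contigs = b_ids,
      b_genes = ann$gene_id[ann$contig_id %in% b_ids],
      cooccurrence_contigs = if (config$b_specific_fraction > 0) b_ids
                             else character(0),
      sat_arrays = sats)

    list(contigs = contig_set(contigs), annotation = ann, truth = truth,
         repeats = c(sat_A = sat_A, sat_B = sat_B, unlist(fams)))
  })
}

#' Read simulation configuration
#'
#' @param read_len read length in bp (150, single-end; paired-end sequencing
#'   adds nothing to alignment-free k-mer counting).
#' @param coverage fold coverage of the sampled genome (20x, the published
#'   library depth).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(read_len = 150L, coverage = 20, error_rate = 0.002,
                            seed = 1L) {
  stopifnot(coverage > 0, read_len > 0)
  list(read_len = as.integer(read_len), coverage = coverage,
       error_rate = error_rate, seed = as.integer(seed))
}

#' Simulate shotgun reads from a set of contigs
#'
#' `round(coverage * total_len / read_len)` single-end reads with uniform
#' start positions (contigs weighted by sequence length), random strand, and
#' i.i.d. substitution errors. A 0B library is simulated from the A contigs
#' only, a +B library from A and B together.
#'
#' @param contigs a [contig_set()] (subset to sample from; must be non-empty).
#' @param config a [read_sim_config()].
#' @return a [read_set()], deterministic given the config seed.
#' @export
simulate_reads <- function(contigs, config = read_sim_config()) {
  if (length(contigs) == 0) stop("cannot simulate reads from an empty contig set")
  with_seed(derive_seed(config$seed, "reads"), {
    rl <- config$read_len
    lens <- nchar(contigs)
    if (any(lens < rl))
      warning("contig(s) shorter than read length; reads clamped to contig")
    total <- sum(lens)
    n_reads <- round(config$coverage * total / rl)
    ci <- sample.int(length(contigs), n_reads, replace = TRUE,
                     prob = lens / total)
    out <- character(n_reads)
    for (i in seq_along(contigs)) {
      sel <- which(ci == i)
      if (!length(sel)) next
      L <- lens[i]
      eff <- min(rl, L)
      starts <- sample.int(max(1L, L - eff + 1L), length(sel), replace = TRUE)
      out[sel] <- substring(contigs[[i]], starts, starts + eff - 1L)
    }
    if (config$error_rate > 0) {
      n_err <- rbinom(n_reads, nchar(out), config$error_rate)
      for (i in which(n_err > 0)) out[i] <- mutate_dna(out[i], config$error_rate)
    }
    flip <- runif(n_reads) < 0.5
    out[flip] <- revcomp(out[flip])
    read_set(out, sprintf("r%07d", seq_len(n_reads)))
  })
}

#' Expression simulation configuration
#'
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline abundance (ln scale; defaults mu = 4, sigma = 1).
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2).
#' @param fold_change planted fold change for up-regulated genes (default 8).
#' @param replicates replicates per (stage, b_status) group (default 3).
#' @param stages stages to simulate.
#' @param spurious_fraction fraction of non-planted B genes that leak
#'   expression into 0B samples (decoys; default 0.02).
#' @param size_factor_range samples' true depth factors are drawn uniformly
#'   from this interval.
#' @return an `expr_sim_config` list.
#' @export
expr_sim_config <- function(baseline_meanlog = 4, baseline_sdlog = 1,
                            dispersion = 0.1, fold_change = 8,
                            replicates = 3L,
                            stages = c("early", "mid", "late", "lcm"),
                            spurious_fraction = 0.02,
                            size_factor_range = c(0.7, 1.4)) {
  stopifnot(dispersion > 0, fold_change > 0)
  list(baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
       dispersion = dispersion, fold_change = fold_change,
       replicates = as.integer(replicates), stages = stages,
       spurious_fraction = spurious_fraction,
       size_factor_range = size_factor_range)
}

#' Simulate a gene count matrix with planted B-gene upregulation
#'
#' Counts are negative binomial with mean `s_j * q_g * FC_gj`. A-located
#' genes have baseline abundance `q_g` in every sample. B-located genes are
#' silent everywhere except: planted genes, which are expressed (at
#' `q_g * fold_change`) in the +B samples of the stages they are planted in;
#' and spurious decoys, which leak baseline expression into all samples
#' including 0B (emulating spurious 0B expression of B-assigned genes).
#'
#' @param config an [expr_sim_config()].
#' @param annotation a [gene_annotation()].
#' @param truth truth list with `b_contigs` (and optionally `spurious_genes`
#'   to fix the decoy set explicitly).
#' @param planted_up named list: stage -> character vector of planted
#'   up-regulated B gene ids.
#' @param seed integer seed.
#' @return list with `cm` (a [count_matrix()]) and `truth` additions
#'   (`de_truth = planted_up`, `spurious_genes`).
#' @export
simulate_counts <- function(config = expr_sim_config(), annotation, truth,
                            planted_up = list(), seed = 1L) {
  bad <- setdiff(unlist(planted_up), annotation$gene_id)
  if (length(bad))
    stop("planted gene(s) absent from annotation: ", paste(bad, collapse = ", "))
  with_seed(derive_seed(seed, "counts"), {
    genes <- annotation$gene_id
    is_b <- annotation$contig_id %in% truth$b_contigs
    q <- stats::rlnorm(length(genes), config$baseline_meanlog,
                       config$baseline_sdlog)
    names(q) <- genes

    spurious <- truth$spurious_genes
    if (is.null(spurious)) {
      cand <- setdiff(genes[is_b], unlist(planted_up))
      n_sp <- round(config$spurious_fraction * sum(is_b))
      spurious <- if (n_sp > 0 && length(cand))
        sample(cand, min(n_sp, length(cand))) else character(0)
    }

    samples <- expand.grid(replicate = seq_len(config$replicates),
                           b_status = c("0B", "+B"), stage = config$stages,
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_%s_r%d", samples$stage,
                                 sub("\\+", "p", samples$b_status),
                                 samples$replicate)
    samples <- samples[, c("sample_id", "stage", "b_status", "replicate")]
    s_j <- runif(nrow(samples), config$size_factor_range[1],
                 config$size_factor_range[2])

    mu <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                 dimnames = list(genes, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      st <- samples$stage[j]; plus <- samples$b_status[j] == "+B"
      base <- q
      base[is_b] <- 0                       # B genes silent by default
      base[spurious] <- q[spurious]         # decoys leak everywhere
      if (plus) {
        pl <- intersect(planted_up[[st]] %||% character(0), genes)
        base[pl] <- q[pl] * config$fold_change
      }
      mu[, j] <- s_j[j] * base
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    cm <- count_matrix(counts, samples)
    list(cm = cm, de_truth = planted_up, spurious_genes = spurious)
  })
}

#' Simulate A/B protein variant pairs with known differences
#'
#' Each pair starts from a random amino-acid sequence; the B variant differs
#' at exactly `n_subs` sampled positions (always to a different residue) and,
#' when flagged, loses a terminal run of `trunc_len` residues.
#'
#' @param n_pairs number of pairs.
#' @param length protein length (residues).
#' @param n_subs substitutions per pair (must be < `length`).
#' @param truncate_flags logical vector (recycled) marking pairs whose B
#'   variant is C-terminally truncated.
#' @param trunc_len residues removed when truncated (default 20% of length).
#' @param seed integer seed.
#' @return list with `pairs` (list of `list(gene, seqA, seqB)`) and
#'   `substitutions_truth` (per pair, data.frame of position/aa_A/aa_B).
#' @export
simulate_protein_pairs <- function(n_pairs, length, n_subs,
                                   truncate_flags = FALSE,
                                   trunc_len = max(1L, round(0.2 * length)),
                                   seed = 1L) {
  if (n_subs >= length) stop("n_subs must be smaller than the protein length")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  truncate_flags <- rep_len(truncate_flags, n_pairs)
  with_seed(derive_seed(seed, "proteins"), {
    pairs <- vector("list", n_pairs)
    truths <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      a <- sample(aa, length, replace = TRUE)
      b <- a
      pos <- sort(sample.int(length, n_subs))
      for (p in pos) b[p] <- sample(setdiff(aa, a[p]), 1)
      if (truncate_flags[i]) b <- b[seq_len(length - trunc_len)]
      pairs[[i]] <- list(gene = sprintf("sim%02d", i),
                         seqA = paste(a, collapse = ""),
                         seqB = paste(b, collapse = ""))
      keep <- pos[pos <= length(b)]
      truths[[i]] <- data.frame(position = keep, aa_A = a[keep], aa_B = b[keep],
                                stringsAsFactors = FALSE)
    }
    list(pairs = pairs, substitutions_truth = truths)
  })
}
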