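test_that("count_kmers matches the window-enumeration oracle", {
  set.seed(101)
  for (case in 1:30) {
    k <- sample(c(11L, 15L, 21L), 1)
    seqs <- replicate(sample(1:3, 1),
                      random_dna_str(sample(k:200, 1), with_n = case %% 3 == 0))
    got <- kmer_counts(count_kmers(seqs, k))
    want <- oracle_count_kmers(seqs, k)
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("counts are invariant under reverse-complementing every sequence", {
  set.seed(102)
  for (case in 1:10) {
    seqs <- replicate(2, random_dna_str(80))
    a <- kmer_counts(count_kmers(seqs, 15))
    b <- kmer_counts(count_kmers(revcomp(seqs), 15))
    expect_identical(a[order(names(a))], b[order(names(b))])
  }
})

test_that("short sequences yield an empty index with a warning", {
  expect_warning(idx <- count_kmers("ACGTACGTAC", 11), "empty")
  expect_identical(idx$n_distinct, 0)
  expect_identical(idx$mass, 0)
})

test_that("diagnostic k-mers are the contig k-mers unique in the assembly", {
  set.seed(103)
  u1 <- random_dna_str(300); u2 <- random_dna_str(300)
  k <- 21L
  # c3 duplicates c2 exactly: every c2/c3 k-mer has assembly count >= 2
  asm <- contig_set(c(c1 = u1, c2 = u2, c3 = u2))
  ref <- count_kmers(asm, k)
  expect_identical(length(find_diagnostic_kmers(u2, ref)), 0L)
  d1 <- find_diagnostic_kmers(u1, ref)
  want <- oracle_count_kmers(c(u1, u2, u2), k)
  u1_kmers <- names(oracle_count_kmers(u1, k))
  expect_setequal(d1, u1_kmers[want[u1_kmers] == 1])
  # a contig that never entered the index is rejected
  expect_error(find_diagnostic_kmers(random_dna_str(100), ref), "absent")
})

test_that("a tandem-array-only contig has (almost) no diagnostic k-mers", {
  set.seed(104)
  mono <- random_dna_str(137)
  array_contig <- strrep(mono, 20)
  asm <- contig_set(c(arr = array_contig, bg = random_dna_str(5000)))
  ref <- count_kmers(asm, 39)
  d <- find_diagnostic_kmers(array_contig, ref)
  # only windows inside the terminal partial copies can be unique
  expect_lt(length(d), 137)
})

test_that("score_contig normalizes by read-set mass with a pseudocount", {
  set.seed(105)
  target <- random_dna_str(400)
  other <- random_dna_str(400)
  asm <- contig_set(c(t = target, o = other))
  k <- 21L
  ref <- count_kmers(asm, k)
  diag <- find_diagnostic_kmers(target, ref)
  # equal-mass read sets containing only the *other* contig: c+ = c0 = 0
  plus <- count_kmers(read_set(other), k)
  zero <- count_kmers(read_set(other), k)
  s <- score_contig(diag, plus, zero, pseudocount = 1)
  expect_identical(s$c_plus, 0)
  expect_identical(s$c_zero, 0)
  expect_identical(s$ratio, 1)       # pseudocount symmetry at equal masses
  # unequal masses: closed form M_zero / M_plus
  plus2 <- count_kmers(read_set(c(other, other)), k)
  s2 <- score_contig(diag, plus2, zero, pseudocount = 1)
  expect_equal(s2$ratio, zero$mass / plus2$mass)
  # empty diagnostic set is flagged, not scored
  expect_true(is.na(score_contig(character(0), plus, zero)$ratio))
})

test_that("classification bands follow the published thresholds", {
  cfg <- run_config()
  lab <- vapply(c(0.9, 1.0, 1.05, 1.1, 5.0), classify_label,
                character(1), n_diag = 1000L, config = cfg)
  expect_identical(lab, c("A", "A", "B_low_confidence",
                          "B_high_confidence", "B_high_confidence"))
  expect_identical(classify_label(5, n_diag = 99L, cfg), "unclassified")
  expect_identical(classify_label(NA_real_, n_diag = 0L, cfg), "unclassified")
})

test_that("welch_ttest matches the reference implementation and is symmetric", {
  w <- welch_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.2878641, tolerance = 1e-6)
  set.seed(106)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), mean = runif(1, 0, 2))
    w <- welch_ttest(x, y)
    ref <- t.test(x, y)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    expect_equal(welch_ttest(y, x)$p, w$p)
  }
  ident <- welch_ttest(c(2, 2), c(2, 2))
  expect_identical(ident$t, 0)
  expect_identical(ident$p, 1)
  degenerate <- welch_ttest(c(2, 2), c(3, 3))
  expect_identical(degenerate$t, -Inf)
  expect_lte(degenerate$p, 1e-300)
})

test_that("classify_assembly is local: dropping B contigs keeps A labels", {
  set.seed(107)
  cfg <- genome_sim_config(n_A = 3, A_len = 12000, n_B = 2, B_len = 8000,
                           segments_per_B = 2, gene_density_B = 0.02,
                           gene_len = 120)
  sim <- simulate_genome(cfg, seed = 9)
  rc <- read_sim_config(error_rate = 0)
  a_ids <- setdiff(names(sim$contigs), sim$truth$b_contigs)
  rc$seed <- 1; r0 <- simulate_reads(sim$contigs[a_ids], rc)
  rc$seed <- 2; rp <- simulate_reads(sim$contigs, rc)
  run_cfg <- run_config(min_diag_kmers = 50)
  full <- classify_assembly(sim$contigs, rp, r0, run_cfg)$classification
  # removing B contigs from the assembly index must not flip any A label
  sub <- classify_assembly(sim$contigs[a_ids], rp, r0, run_cfg)$classification
  expect_identical(sub$label, full$label[match(sub$contig_id, full$contig_id)])
})

test_that("rnaseq_support flags +B-exclusive expression on low-confidence contigs", {
  counts <- rbind(
    gB    = c(0L, 0L, 0L, 40L, 44L, 38L),   # B gene expressed only in +B
    gSpur = c(30L, 28L, 35L, 33L, 31L, 29L),# decoy leaks into 0B
    gA    = c(20L, 22L, 19L, 21L, 20L, 23L))
  colnames(counts) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = colnames(counts), stage = "mid",
                     b_status = rep(c("0B", "+B"), each = 3),
                     replicate = rep(1:3, 2))
  cm <- count_matrix(counts, meta)
  ann <- gene_annotation(c("gB", "gSpur", "gA"), c("b1", "b2", "a1"),
                         c(1L, 1L, 1L), c(300L, 300L, 300L))
  cls <- data.frame(contig_id = c("b1", "b2", "a1", "empty"),
                    label = c("B_low_confidence", "B_low_confidence", "A",
                              "B_low_confidence"),
                    stringsAsFactors = FALSE)
  out <- rnaseq_support(cls, cm, ann)
  expect_identical(out$rnaseq_support,
                   c("supported", "not_supported", "not_supported",
                     "not_applicable"))
})

test_that("more B-specific sequence never lowers a B contig's mean ratio", {
  # 3-point sweep over b_specific_fraction with paired seeds; the diagnostic
  # ratio of a B contig grows with its novel (B-only) content in expectation
  mean_ratio <- function(frac, seed) {
    cfg <- genome_sim_config(n_A = 3, A_len = 12000, n_B = 2, B_len = 12000,
                             segments_per_B = 2, gene_len = 150,
                             gene_density_B = 0.02,
                             b_specific_fraction = frac)
    sim <- simulate_genome(cfg, seed)
    rc <- read_sim_config(error_rate = 0)
    a_ids <- setdiff(names(sim$contigs), sim$truth$b_contigs)
    rc$seed <- derive_seed(seed, "mono0")
    r0 <- simulate_reads(sim$contigs[a_ids], rc)
    rc$seed <- derive_seed(seed, "monoP")
    rp <- simulate_reads(sim$contigs, rc)
    cls <- classify_assembly(sim$contigs, rp, r0,
                             run_config(min_diag_kmers = 50))$classification
    mean(cls$ratio[cls$contig_id %in% sim$truth$b_contigs])
  }
  for (seed in 1:2) {
    sweep <- vapply(c(0.2, 0.35, 0.5), mean_ratio, numeric(1), seed = seed)
    expect_true(all(diff(sweep) > 0))
  }
})
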