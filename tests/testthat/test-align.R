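test_that("identical sequences score the diagonal sum at 100% identity", {
  sch <- scoring_scheme()
  s <- "MKTAYIAKQRQISFVK"
  aln <- global_align_affine(s, s, sch)
  res <- strsplit(s, "")[[1]]
  expect_equal(aln$score, sum(sch$matrix[cbind(res, res)]))
  expect_equal(aln$identity_pct, 100)
  expect_identical(aln$gap_columns, 0L)
  expect_identical(aln$aligned_A, s)
})

test_that("DP score equals exhaustive enumeration on short random pairs", {
  sch <- scoring_scheme()
  set.seed(31)
  for (i in 1:60) {
    a <- random_protein(sample(1:6, 1))
    b <- random_protein(sample(1:6, 1))
    got <- global_align_affine(a, b, sch)$score
    expect_equal(got, oracle_align_score(a, b, sch),
                 info = paste(a, b))
  }
})

test_that("swapping inputs preserves the score; identity too when co-optima are benign", {
  sch <- scoring_scheme()
  set.seed(32)
  for (i in 1:20) {
    a <- random_protein(sample(3:40, 1))
    b <- random_protein(sample(3:40, 1))
    expect_equal(global_align_affine(a, b, sch)$score,
                 global_align_affine(b, a, sch)$score)
  }
  # for realistic (high-similarity) variant pairs the optimum is unique, so
  # identity is swap-invariant as well
  pp <- simulate_protein_pairs(10, length = 120, n_subs = 3,
                               truncate_flags = c(FALSE, TRUE), seed = 32)
  for (p in pp$pairs) {
    ab <- global_align_affine(p$seqA, p$seqB, sch)
    ba <- global_align_affine(p$seqB, p$seqA, sch)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity_pct, ba$identity_pct)
  }
})

test_that("identity is 100 iff the sequences are equal", {
  set.seed(33)
  for (i in 1:20) {
    a <- random_protein(20)
    b <- random_protein(20)
    aln <- global_align_affine(a, b)
    expect_identical(aln$identity_pct == 100, a == b)
  }
})

test_that("alignment invariants hold: gap stripping recovers inputs", {
  set.seed(34)
  for (i in 1:15) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    aln <- global_align_affine(a, b)
    expect_identical(gsub("-", "", aln$aligned_A, fixed = TRUE), a)
    expect_identical(gsub("-", "", aln$aligned_B, fixed = TRUE), b)
    ac <- strsplit(aln$aligned_A, "")[[1]]
    bc <- strsplit(aln$aligned_B, "")[[1]]
    expect_false(any(ac == "-" & bc == "-"))
  }
  expect_error(global_align_affine("MKX!", "MK"), "illegal residue")
})

test_that("polymorphism listing labels substitutions, indels and truncations", {
  aln <- global_align_affine("IKLMNPQRST", "VKLMNPQRST")
  poly <- list_polymorphisms(aln)
  expect_identical(poly$kind, "substitution")
  expect_identical(poly$label, "I1V")

  # B missing the last 20 of 100 residues: one terminal truncation
  set.seed(35)
  a <- random_protein(100)
  b <- substr(a, 1, 80)
  aln2 <- global_align_affine(a, b)
  poly2 <- list_polymorphisms(aln2, trunc_min = 10)
  expect_identical(poly2$kind, "terminal_truncation")
  expect_identical(poly2$length, 20L)
  expect_equal(aln2$identity_pct, 80)

  none <- list_polymorphisms(global_align_affine(a, a))
  expect_identical(nrow(none), 0L)
})

test_that("variant report handles multiple copies and missing A variants", {
  set.seed(36)
  a <- random_protein(60)
  variants <- list(
    list(gene = "gX", copy = 1L, seqA = a, seqB = a),
    list(gene = "gX", copy = 2L, seqA = a, seqB = a),
    list(gene = "gY", copy = 1L, seqA = NULL, seqB = random_protein(40)))
  tab <- compare_variant_pairs(variants)
  expect_identical(tab$identity_pct[tab$gene == "gX"], c(100, 100))
  expect_identical(tab$labels[tab$gene == "gY"], "missing_A_variant")
  # identical B copies give identical rows (modulo the copy number)
  r1 <- tab[1, -2]; r2 <- tab[2, -2]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
})

test_that("synthetic supplementary-style fixture reproduces the worked identities", {
  fa <- system.file("extdata", "proteins_synthetic.fa", package = "bchrom")
  tab <- compare_variant_pairs(read_protein_variants(fa))
  cen <- tab[tab$gene == "CENH3", ]
  expect_equal(round(cen$identity_pct, 1), 98.7)
  expect_identical(cen$n_substitutions, 2L)
  expect_identical(cen$labels, "I92V;I144M")
  expect_equal(round(tab$identity_pct[tab$gene == "DEAH11"], 2), 99.01)
  esd <- tab[tab$gene == "ESD4", ]
  expect_equal(round(esd$identity_pct[esd$copy == 1], 2), 40.82)
  expect_true(esd$truncated[esd$copy == 1])
  suv <- tab[tab$gene == "SUVH5", ]
  expect_equal(suv$identity_pct, 100)
  expect_identical(suv$n_substitutions, 0L)
})
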