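test_that("annotation closure follows the true-path rule", {
  dag <- ontology_dag(c("c", "b"), c("b", "a"))
  m <- propagate_annotations(gene_term_map(list(g = "c"), dag), dag)
  expect_identical(m$g, c("a", "b", "c"))
  # diamond: d -> {b, c} -> a; ancestors counted once
  dia <- ontology_dag(c("d", "d", "b", "c"), c("b", "c", "a", "a"))
  md <- propagate_annotations(gene_term_map(list(g = "d"), dia), dia)
  expect_identical(md$g, c("a", "b", "c", "d"))
  # idempotence on random DAGs (edges only from higher to lower index)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    terms <- sprintf("t%02d", 1:n)
    ch <- c(); pa <- c()
    for (child in 2:n) {
      for (parent in sample(1:(child - 1), sample(1:min(2, child - 1), 1)))
        { ch <- c(ch, terms[child]); pa <- c(pa, terms[parent]) }
    }
    dag <- ontology_dag(ch, pa)
    genes <- setNames(lapply(1:4, function(.) sample(terms, 2)),
                      paste0("g", 1:4))
    once <- propagate_annotations(gene_term_map(genes, dag), dag)
    twice <- propagate_annotations(once, dag)
    expect_identical(unclass(twice), unclass(once))
  }
  expect_error(ontology_dag(c("a", "b"), c("b", "a")), "cycle")
})

test_that("hypergeometric p matches closed form and exhaustive enumeration", {
  # N=10, K=4, n=5, k=4  ->  p = 6/252
  dag <- ontology_dag("T", "root")
  uni <- sprintf("u%02d", 1:10)
  map <- gene_term_map(setNames(lapply(1:4, function(.) "T"), uni[1:4]), dag)
  closed <- propagate_annotations(map, dag)
  study <- uni[c(1:4, 10)]   # 4 annotated of 5 drawn
  res <- hypergeom_enrich(study, uni, closed)
  expect_equal(res$p[res$term_id == "T"], 6 / 252)
  expect_identical(res$k[res$term_id == "T"], 4L)

  # study = universe: every term has k = K and p = 1
  res_all <- hypergeom_enrich(uni, uni, closed)
  expect_true(all(res_all$p == 1))

  # equality with the draw-enumeration oracle for all N <= 12
  set.seed(22)
  for (i in 1:25) {
    N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- sprintf("u%02d", 1:N)
    map <- gene_term_map(setNames(lapply(seq_len(K), function(.) "T"),
                                  uni[1:K]), dag)
    closed <- propagate_annotations(map, dag)
    study <- sample(uni, n)
    res <- hypergeom_enrich(study, uni, closed)
    k <- sum(study %in% uni[1:K])
    expect_equal(res$p[res$term_id == "T"], oracle_hyper_enum(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich(c("u01", "zz"), uni, closed), "outside")
})

test_that("p is monotonically non-increasing in k at fixed (N, K, n)", {
  for (k in 0:5) {
    p <- stats::phyper(0:5 - 1, 6, 14, 8, lower.tail = FALSE)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("restricted universe: equal study/universe frequency gives p near 1", {
  # every universe gene annotated to T: study frequency equals universe
  # frequency no matter the study, so T can never look enriched
  dag <- ontology_dag("T", "root")
  uni <- sprintf("u%02d", 1:20)
  map <- gene_term_map(setNames(lapply(uni, function(.) "T"), uni), dag)
  closed <- propagate_annotations(map, dag)
  res <- hypergeom_enrich(uni[1:7], uni, closed)
  expect_equal(res$p[res$term_id == "T"], 1)
})

test_that("terminal selection keeps significant terms without significant descendants", {
  dag <- ontology_dag(c("child", "mid"), c("mid", "top"))
  res <- data.frame(term_id = c("top", "mid", "child"),
                    k = 1L, K = 1L, n = 1L, N = 2L,
                    p = c(0.01, 0.2, 0.01),
                    significant = c(TRUE, FALSE, TRUE))
  out <- select_terminal_significant(res, dag, 0.05)
  expect_identical(out$terminal_significant[out$term_id == "child"], TRUE)
  expect_identical(out$terminal_significant[out$term_id == "top"], FALSE)
  # parent significant, child not: parent is terminal
  res2 <- res; res2$p <- c(0.01, 0.2, 0.2)
  out2 <- select_terminal_significant(res2, dag, 0.05)
  expect_identical(out2$terminal_significant[out2$term_id == "top"], TRUE)
  # invariant to result row order
  perm <- res[c(3, 1, 2), ]
  expect_identical(select_terminal_significant(perm, dag, 0.05), out)
})

test_that("stage overlap tallies match membership enumeration", {
  sets <- list(early = c("a", "b"), mid = c("b", "c"), late = "b")
  out <- stage_overlaps(sets)
  expect_identical(out$count[out$pattern == "early&mid&late"], 1L)
  expect_identical(sum(out$count), 3L)  # |union|
  disj <- stage_overlaps(list(x = c("a"), y = c("b")))
  expect_true(all(disj$count == 1L))
  expect_true(!any(grepl("&", disj$pattern)))
  set.seed(23)
  for (i in 1:10) {
    sets <- list(s1 = sample(letters, 8), s2 = sample(letters, 5),
                 s3 = sample(letters, 12))
    out <- oracle_overlap_counts(sets)
    got <- stage_overlaps(sets)
    expect_identical(setNames(got$count, got$pattern)[names(out)],
                     setNames(as.integer(out), names(out)))
    expect_identical(sum(got$count), length(unique(unlist(sets))))
  }
  expect_error(stage_overlaps(list(a = "x")), "at least 2")
})

test_that("candidate table dedups genes, filters by terms, requires config", {
  dag <- ontology_dag(c("Tm", "Tl"), c("root", "root"))
  map <- gene_term_map(list(g1 = "Tm", g2 = "Tm", g3 = "Tl"), dag)
  closed <- propagate_annotations(map, dag)
  enr <- data.frame(term_id = c("Tm", "Tl"), k = 2L, K = 2L, n = 2L, N = 5L,
                    p = 0.01, significant = TRUE,
                    terminal_significant = TRUE)
  tab <- build_candidate_table(
    enrich_by_stage = list(mid = enr, late = enr),
    up_by_stage = list(mid = c("g1", "g2", "gNoTerm"), late = "g1"),
    lcm_enrich = NULL, lcm_up = character(0),
    relevant_terms = "Tm", closed_map = closed)
  expect_identical(tab$gene_id, c("g1", "g2"))
  expect_identical(tab$stages_detected[tab$gene_id == "g1"], "late;mid")
  expect_false(any(tab$gene_id == "gNoTerm"))   # no relevant annotation
  expect_false(any(tab$gene_id == "g3"))        # Tl not in relevant_terms
  expect_error(
    build_candidate_table(list(), list(), NULL, character(0),
                          relevant_terms = character(0), closed_map = closed),
    "non-empty")
})
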