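test_that("median-of-ratios size factors recover depth ratios", {
  counts <- matrix(c(10L, 100L, 30L, 300L), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors_median_ratio(counts)
  expect_equal(unname(sf[2] / sf[1]), 3)
  # identical samples: equal factors
  counts2 <- cbind(s1 = c(5L, 9L), s2 = c(5L, 9L))
  rownames(counts2) <- c("g1", "g2")
  sf2 <- size_factors_median_ratio(counts2)
  expect_equal(unname(sf2[1]), unname(sf2[2]))
  # appending a gene with a zero anywhere must not change the factors
  counts3 <- rbind(counts, gz = c(0L, 17L))
  expect_equal(size_factors_median_ratio(counts3), sf)
  # all genes carry a zero somewhere: explicit failure
  allz <- matrix(c(0L, 3L, 4L, 0L), 2, dimnames = list(c("g1", "g2"),
                                                       c("s1", "s2")))
  expect_error(size_factors_median_ratio(allz), "pseudocount")
})

de_world <- function(n, planted = character(0), seed = 1,
                     stages = "mid") {
  ann <- flat_annotation(n)
  sc <- simulate_counts(expr_sim_config(stages = stages,
                                        spurious_fraction = 0),
                        ann, list(b_contigs = character(0)),
                        planted_up = if (length(planted))
                          setNames(list(planted), stages[1]) else list(),
                        seed = seed)
  sc$cm
}

test_that("de_test calls nothing on identical group means and errors on tiny groups", {
  cm <- de_world(200, seed = 11)
  de <- de_test(cm, "mid")
  expect_true(all(de$call %in% c("ns", "up", "down")))
  # the DEResult invariant: calls match thresholds exactly
  cfg <- run_config()
  expect_identical(de$call == "up",
                   de$log2fc >= cfg$lfc_threshold & de$p <= cfg$p_threshold)
  expect_identical(de$call == "down",
                   de$log2fc <= -cfg$lfc_threshold & de$p <= cfg$p_threshold)
  one_rep <- cm
  keep <- c(which(one_rep$samples$b_status == "0B")[1],
            which(one_rep$samples$b_status == "+B"))
  one_rep$counts <- one_rep$counts[, keep]
  one_rep$samples <- one_rep$samples[keep, ]
  expect_error(de_test(one_rep, "mid"), "0B")
})

test_that("scaling one sample's counts scales its size factor and keeps log2fc", {
  cm <- de_world(300, seed = 12)
  # strictly positive submatrix for exactness
  pos <- rowSums(cm$counts == 0) == 0
  cm$counts <- cm$counts[pos, , drop = FALSE]
  base <- de_test(cm, "mid")
  scaled <- cm
  scaled$counts[, 1] <- scaled$counts[, 1] * 5L
  sf_base <- size_factors_median_ratio(cm$counts)
  sf_scaled <- size_factors_median_ratio(scaled$counts)
  # the scaled sample's factor grows by exactly 5 relative to every other
  # sample (the estimator's reference, a pooled geometric mean, absorbs a
  # common 5^(1/m) drift)
  expect_equal(unname((sf_scaled[1] / sf_scaled[-1]) /
                        (sf_base[1] / sf_base[-1])),
               rep(5, ncol(cm$counts) - 1), tolerance = 1e-12)
  # fold changes are invariant up to the +1 pseudocount's sensitivity to the
  # common drift; calls do not move
  res <- de_test(scaled, "mid")
  expect_equal(res$log2fc, base$log2fc, tolerance = 0.05)
  expect_identical(res$call, base$call)
})

test_that("match_to_b_contigs filters, preserves order, warns on unknowns", {
  ann <- gene_annotation(c("g1", "g2", "g3"), c("B_01", "A_01", "B_02"),
                         c(1L, 1L, 1L), c(10L, 10L, 10L))
  expect_identical(match_to_b_contigs(c("g3", "g1", "g2"), ann,
                                      c("B_01", "B_02")), c("g3", "g1"))
  expect_identical(match_to_b_contigs(c("g1", "g2"), ann, character(0)),
                   character(0))
  expect_warning(out <- match_to_b_contigs(c("g1", "ghost"), ann, "B_01"),
                 "unannotated")
  expect_identical(out, "g1")
})

test_that("null p-values are roughly uniform (KS) and calls deterministic", {
  cm <- de_world(2500, seed = 13)
  de1 <- de_test(cm, "mid")
  de2 <- de_test(cm, "mid")
  expect_identical(de1, de2)
  ks <- suppressWarnings(stats::ks.test(de1$p, "punif")$statistic)
  expect_lt(unname(ks), 0.1)
})
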