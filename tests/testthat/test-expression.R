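test_that("RPKM follows the exact normalisation formula", {
  # two genes; library size = column sum
  cnt <- matrix(c(10, 999990, 5, 999995), nrow = 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  r <- rpkm(cnt, c(1000, 50000))
  expect_equal(r["a", "s1"], 10 * 1e9 / (1e6 * 1000))  # = 10
  expect_equal(r["a", "s2"], 5 * 1e9 / (1e6 * 1000))
  expect_error(rpkm(cnt, c(0, 1000)), "length")
  expect_error(rpkm(cbind(c(0, 0)), c(10, 10)), "library")
})

test_that("equal counts and lengths give equal RPKM", {
  cnt <- matrix(50, nrow = 4, ncol = 3)
  r <- rpkm(cnt, rep(2000, 4))
  expect_true(all(r == r[1, 1]))
})

test_that("sex-bias thresholds are strict and edge cases handled", {
  expect_equal(as.character(classify_sex_bias(3, 1.5)), "female")   # ratio 2
  expect_equal(as.character(classify_sex_bias(1, 2)), "male")       # ratio 0.5
  expect_equal(as.character(classify_sex_bias(1.5, 1)), "unbiased") # exactly 1.5
  expect_equal(as.character(classify_sex_bias(0.66, 1)), "unbiased")# exactly 0.66
  expect_equal(as.character(classify_sex_bias(1, 0)), "female")     # infinite
  b <- classify_sex_bias(0, 0)
  expect_equal(as.character(b), "unbiased")
  expect_true(attr(b, "unexpressed"))
  expect_error(classify_sex_bias(-1, 2), "nonnegative")
})

test_that("tissue-bias thresholding matches the FDR and fold-change rules", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   log2FC = c(2, -2, 3, 1.2, 2),
                   padj = c(0.01, 0.01, 0.2, 0.01, NA))
  expect_warning(tb <- classify_tissue_bias(de), "missing")
  expect_equal(unname(tb[c("a", "b", "c", "d")]),
               c("ovary", "gut", "none", "none"))
})

test_that("enrichment test reproduces the Pearson chi-square by hand", {
  # Z/autosome x gut/ovary counts
  tab <- matrix(c(6, 153, 6, 40), nrow = 2,
                dimnames = list(c("Z", "autosome"), c("gut", "ovary")))
  ht <- suppressWarnings(enrichment_test(tab))
  # independent hand computation of the Pearson statistic
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(ht$statistic), sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_lt(ht$p.value, 0.05)
  # proportional table: statistic 0, p 1
  ht0 <- enrichment_test(matrix(c(10, 20, 30, 60), 2))
  expect_equal(unname(ht0$statistic), 0, tolerance = 1e-12)
  expect_equal(ht0$p.value, 1)
  expect_equal(unname(enrichment_test(matrix(10, 2, 2))$statistic), 0)
  expect_error(enrichment_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("annotation partitions expressed genes into the three bias classes", {
  tr <- sim_truth(n_genes = 400, seed = 15)
  sim <- simulate_counts(tr)
  ex <- simulate_expression(sim, bias_fold = 4)
  an <- annotate_genes(ex$counts, ex$samples, ex$gene_lengths)
  expect_true(all(an$bias %in% c("female", "male", "unbiased")))
  expect_equal(nrow(an), nrow(sim))
})

test_that("classification is invariant to library-size rescaling", {
  tr <- sim_truth(n_genes = 200, seed = 16)
  sim <- simulate_counts(tr)
  ex <- simulate_expression(sim, bias_fold = 3)
  an1 <- annotate_genes(ex$counts, ex$samples, ex$gene_lengths)
  cnt2 <- ex$counts
  cnt2[, 1] <- cnt2[, 1] * 7L   # one library scaled
  an2 <- annotate_genes(cnt2, ex$samples, ex$gene_lengths)
  expect_identical(an1$bias, an2$bias)
})
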