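test_that("single Phe codon yields L_s = 1/3, L_n = 8/3", {
  aln <- make_aln(rep("TTT", 4), "TTT")
  cs <- count_sites(aln)
  expect_equal(cs$L_s, 1 / 3)
  expect_equal(cs$L_n, 8 / 3)
  expect_equal(cs$codons_used, 1L)
})

test_that("codons with N or gaps are excluded entirely", {
  aln <- make_aln(c("TTTAAA", "TTTAAA", "TNTAAA", "TTTAAA"), "TTTAAA")
  cs <- count_sites(aln)
  # first codon excluded, AAA (Lys) remains: 1 syn change at pos 3 (AAG)
  expect_equal(cs$codons_used, 1L)
  expect_equal(cs$L_s + cs$L_n, 3)
  expect_equal(cs$L_s, 1 / 3)
})

test_that("site counts are conserved: L_n + L_s = 3 * codons_used", {
  tr <- sim_truth(n_genes = 8, mean_codons = 80, seed = 31)
  alns <- emit_alignments(simulate_counts(tr))
  gc <- gene_counts_from_alignments(alns)
  expect_equal(gc$L_n + gc$L_s, 3 * gc$codons_used, tolerance = 1e-9)
})

test_that("a single fixed difference is classified through the genetic code", {
  # ATG (Met) vs outgroup ATA (Ile): nonsynonymous fixed difference
  aln <- make_aln(rep("ATG", 4), "ATA")
  gc <- count_alignment(aln)
  expect_equal(gc$D_n, 1)
  expect_equal(gc$D_s, 0)
  # GGA vs GGG (Gly): synonymous
  aln <- make_aln(rep("GGA", 4), "GGG")
  gc <- count_alignment(aln)
  expect_equal(gc$D_s, 1)
  expect_equal(gc$D_n, 0)
})

test_that("a single synonymous SNP lands in the right SFS bin", {
  # third-position T/C in Phe codon (TTT/TTC both Phe), outgroup TTT
  aln <- make_aln(c("TTC", "TTT", "TTT", "TTT"), "TTT")
  gc <- count_alignment(aln)
  expect_equal(gc$P_s, 1)
  expect_equal(gc$P_n, 0)
  expect_equal(unname(attr(gc, "sfs_s")[1, ]), c(1L, 0L, 0L))
  expect_equal(gc$D_s + gc$D_n, 0)
})

test_that("identical ingroup and outgroup give all-zero counts", {
  aln <- make_aln(rep("ATGGTTCCA", 5), "ATGGTTCCA")
  gc <- count_alignment(aln)
  expect_equal(gc$P_n + gc$P_s + gc$D_n + gc$D_s, 0)
  expect_equal(gc$pi_n, 0)
  expect_equal(gc$pi_s, 0)
})

test_that("sites both polymorphic and divergent count as polymorphism only", {
  # ingroup segregates T/C at pos 3; outgroup carries A (absent in ingroup)
  aln <- make_aln(c("TTC", "TTT", "TTT", "TTT"), "TTA")
  gc <- count_alignment(aln)
  expect_equal(gc$P_s + gc$P_n, 1)
  expect_equal(gc$D_s + gc$D_n, 0)
  # unpolarisable: recorded in the folded bin
  expect_equal(unname(attr(gc, "polarization")), c(0L, 1L))
})

test_that("fewer than 4 ingroup sequences is an error", {
  aln <- make_aln(c("TTT", "TTT"), "TTT")
  expect_error(count_alignment(aln), "at least 4")
})

test_that("pairwise diversity equals the brute-force average over pairs", {
  tr <- sim_truth(n_genes = 6, mean_codons = 100, theta_s = 0.02, seed = 17)
  sim <- simulate_counts(tr)
  alns <- emit_alignments(sim)
  gc <- gene_counts_from_alignments(alns)
  for (g in seq_along(alns)) {
    aln <- read_codon_alignment(alns[[g]])
    n <- nrow(aln$ing)
    diffs <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      diffs <- diffs + sum(aln$ing[i, ] != aln$ing[j, ])
    brute_total <- diffs / choose(n, 2)
    ours_total <- gc$pi_n[g] * gc$L_n[g] + gc$pi_s[g] * gc$L_s[g]
    expect_equal(ours_total, brute_total, tolerance = 1e-9)
  }
})

test_that("tri-allelic site heterozygosity matches the pairwise definition", {
  # pos 3 of CCT (Pro, 4-fold): alleles T/T/C/A/A/G among 6 sequences
  ing <- c("CCT", "CCT", "CCC", "CCA", "CCA", "CCG")
  aln <- make_aln(ing, "CCT")
  gc <- count_alignment(aln)
  n <- 6
  diffs <- 0
  m <- do.call(rbind, strsplit(ing, ""))
  for (i in 1:5) for (j in (i + 1):6) diffs <- diffs + sum(m[i, ] != m[j, ])
  expect_equal(gc$pi_s * gc$L_s + gc$pi_n * gc$L_n, diffs / choose(n, 2),
               tolerance = 1e-9)
  expect_equal(gc$P_s, 3)  # three derived alleles, all synonymous
})

test_that("pooling doubles counts but preserves ratio statistics", {
  tr <- sim_truth(n_genes = 4, seed = 3)
  sim <- simulate_counts(tr)
  idx <- c(seq_len(nrow(sim)), seq_len(nrow(sim)))
  p1 <- fastz:::pool_rows(sim)
  p2 <- fastz:::pool_rows(sim, idx)
  expect_equal(p2$P_s, 2 * p1$P_s)
  expect_equal(p2$D_n, 2 * p1$D_n)
  expect_equal(p2$dN / p2$dS, p1$dN / p1$dS)
  expect_equal(p2$pi_s, p1$pi_s)
})

test_that("pool_counts recomputes ratios from sums within groups", {
  tr <- sim_truth(n_genes = 60, seed = 8)
  sim <- simulate_counts(tr)
  pooled <- pool_counts(sim, sim$chrom_class)
  expect_setequal(pooled$group, c("Z", "autosome"))
  for (g in pooled$group) {
    idx <- which(sim$chrom_class == g)
    expect_equal(pooled$dN[pooled$group == g],
                 sum(sim$D_n[idx]) / sum(sim$L_n[idx]))
  }
  expect_equal(sum(pooled$n_genes), nrow(sim))
})

test_that("mixed ingroup sample sizes are rejected", {
  a1 <- make_aln(rep("TTTAAA", 4), "TTTAAA", "g1")
  a2 <- make_aln(rep("TTTAAA", 5), "TTTAAA", "g2")
  expect_error(gene_counts_from_alignments(list(a1, a2)), "mixed")
})
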