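test_that("truth validation names the offending field", {
  expect_error(sim_truth(theta_s = -1), "theta_s")
  expect_error(sim_truth(p_adaptive = 1), "p_adaptive")
  expect_error(sim_truth(ne_ratio_Z = 0), "ne_ratio_Z")
  expect_error(sim_truth(gamma_mean_S = 5), "gamma_mean_S")
  expect_error(sim_truth(gamma_shape = 0), "gamma_shape")
})

test_that("identical seed reproduces simulated counts exactly", {
  tr <- sim_truth(n_genes = 40, seed = 42)
  a <- simulate_counts(tr)
  b <- simulate_counts(tr)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "sfs_s"), attr(b, "sfs_s"))
  expect_identical(attr(a, "sfs_n"), attr(b, "sfs_n"))
})

test_that("neutral DFE makes pooled spectra proportional to site totals", {
  tr <- sim_truth(n_genes = 1500, gamma_mean_S = 0, p_adaptive = 0,
                  theta_s = 0.03, seed = 9)
  sim <- simulate_counts(tr)
  p <- fastz:::pool_rows(sim)
  ratio <- p$sfs_n / p$sfs_s
  # L_n/L_s = 3 by construction, every frequency class
  expect_true(all(abs(ratio / 3 - 1) < 0.1))
})

test_that("mean pooled divergence matches the gamma-DFE fixation integral", {
  shape <- 0.4; meanS <- -800
  tr <- sim_truth(n_genes = 3000, gamma_shape = shape, gamma_mean_S = meanS,
                  p_adaptive = 0, seed = 5)
  # independent oracle: adaptive quadrature over the gamma DFE
  scl <- -meanS / shape
  oracle <- integrate(function(T) dgamma(T, shape, scale = scl) *
                        ifelse(T < 1e-9, 1, T / expm1(T)), 0, Inf,
                      rel.tol = 1e-10)$value
  expect_equal(tr$omega_na_true, oracle, tolerance = 1e-6)
  sim <- simulate_counts(tr)
  p <- fastz:::pool_rows(sim)
  expect_equal(p$D_n / (p$L_n * tr$div_s), oracle, tolerance = 0.05)
})

test_that("increasing the adaptive fraction increases mean divergence", {
  means <- vapply(c(0, 0.3, 0.6), function(p) {
    tr <- sim_truth(n_genes = 800, p_adaptive = p, seed = 7)
    sim <- simulate_counts(tr)
    mean(sim$D_n / sim$L_n)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("pooled synonymous SFS follows the Watterson theta*L/i expectation", {
  tr <- sim_truth(n_genes = 1500, gamma_mean_S = 0, frac_z = 0,
                  theta_s = 0.02, seed = 21)
  sim <- simulate_counts(tr)
  p <- fastz:::pool_rows(sim)
  expected <- tr$theta_s * p$L_s / seq_len(tr$n_alleles - 1)
  # Poisson error: each bin within ~4 sd
  z <- (p$sfs_s - expected) / sqrt(expected)
  expect_true(all(abs(z) < 4))
})

test_that("Z polymorphism is scaled by ne_ratio_Z but divergence is not", {
  tr <- sim_truth(n_genes = 3000, gamma_mean_S = 0, ne_ratio_Z = 0.5,
                  seed = 13)
  sim <- simulate_counts(tr)
  pz <- fastz:::pool_rows(sim, which(sim$chrom_class == "Z"))
  pa <- fastz:::pool_rows(sim, which(sim$chrom_class == "autosome"))
  expect_equal((pz$P_s / pz$L_s) / (pa$P_s / pa$L_s), 0.5, tolerance = 0.05)
  expect_equal(pz$dS / pa$dS, 1, tolerance = 0.05)
})

test_that("expression simulation validates inputs and yields zero RPKM for zero counts", {
  tr <- sim_truth(n_genes = 30, seed = 2)
  sim <- simulate_counts(tr)
  expect_error(simulate_expression(sim, bias_fold = 0.5), "bias_fold")
  expect_error(simulate_expression(sim, n_samples_per_sex = 1),
               "n_samples_per_sex")
  ex <- simulate_expression(sim, n_samples_per_sex = 3, bias_fold = 2)
  cnt <- ex$counts
  cnt[1, ] <- 0L
  r <- rpkm(cnt, ex$gene_lengths)
  expect_true(all(r[1, ] == 0))
})
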