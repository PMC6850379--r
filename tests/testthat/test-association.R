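test_that("identical diversity across classes gives ratio one, scale-invariantly", {
  gc <- make_gc(pi_s = rep(0.02, 10), pi_n = rep(0.002, 10),
                chrom_class = rep(c("Z", "autosome"), 5))
  expect_equal(diversity_ratio(gc)$ratio, 1)
  gc2 <- make_gc(pi_s = rep(0.02 * 5, 10), pi_n = rep(0.002 * 5, 10),
                 chrom_class = rep(c("Z", "autosome"), 5))
  expect_equal(diversity_ratio(gc2)$ratio, 1)
  gc3 <- make_gc(pi_s = rep(0.02, 4), pi_n = rep(0.002, 4),
                 chrom_class = rep("Z", 4))
  expect_error(diversity_ratio(gc3), "both chromosome classes")
})

test_that("simulated effective-size scaling is recovered in the diversity ratio", {
  tr <- sim_truth(n_genes = 1500, gamma_mean_S = 0, p_adaptive = 0,
                  ne_ratio_Z = 0.44, seed = 44)
  sim <- simulate_counts(tr)
  dr <- diversity_ratio(sim, n_bootstrap = 100, seed = 1)
  expect_equal(dr$ratio, 0.44, tolerance = 0.05)
  expect_lt(dr$lower, dr$ratio)
  expect_gt(dr$upper, dr$ratio)
})

test_that("exact linear construction is recovered exactly by the regression", {
  set.seed(8)
  G <- 80
  pi_s <- exp(rnorm(G, -3.6, 0.5))
  gc <- data.frame(pi_n = 0.1 * pi_s, pi_s = pi_s,
                   chrom_class = rep(c("Z", "autosome"), G / 2),
                   mean_rpkm = exp(rnorm(G, 3, 1)))
  # the construction is exact, so lm warns about a perfect fit
  fit <- suppressWarnings(pin_regression(gc))
  co <- coef(fit)
  expect_equal(unname(co["log_pi_s"]), 1, tolerance = 1e-9)
  expect_equal(unname(co["log_rpkm"]), 0, tolerance = 1e-9)
  expect_equal(fit$n_genes_dropped_zero, 0)
})

test_that("a known negative expression coefficient is recovered within 2 SE", {
  set.seed(9)
  G <- 400
  pi_s <- exp(rnorm(G, -3.6, 0.4))
  lrpkm <- rnorm(G, 3, 1)
  z <- rep(c(1, 0), G / 2)
  log_pi_n <- -2 + 1 * log(pi_s) - 0.3 * z - 0.25 * lrpkm + rnorm(G, 0, 0.3)
  gc <- data.frame(pi_n = exp(log_pi_n), pi_s = pi_s,
                   chrom_class = ifelse(z == 1, "Z", "autosome"),
                   mean_rpkm = exp(lrpkm))
  fit <- pin_regression(gc)
  est <- fit$coefficients["log_rpkm", ]
  expect_lt(abs(est$Estimate - (-0.25)), 2 * est$`Std. Error`)
  expect_lt(est$Estimate, 0)
})

test_that("zero-diversity genes are excluded and counted; residuals centre on zero", {
  set.seed(10)
  G <- 60
  gc <- data.frame(pi_n = c(rep(0, 10), exp(rnorm(G - 10, -6, 0.5))),
                   pi_s = exp(rnorm(G, -3.6, 0.5)),
                   chrom_class = rep(c("Z", "autosome"), G / 2),
                   mean_rpkm = exp(rnorm(G, 3, 1)))
  fit <- pin_regression(gc)
  expect_equal(fit$n_genes_used + fit$n_genes_dropped_zero, G)
  expect_equal(fit$n_genes_dropped_zero, 10)
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-12)
})

test_that("single-class designs are rejected as rank deficient", {
  set.seed(11)
  gc <- data.frame(pi_n = exp(rnorm(30, -6, 0.5)),
                   pi_s = exp(rnorm(30, -3.6, 0.5)),
                   chrom_class = "autosome",
                   mean_rpkm = exp(rnorm(30, 3, 1)))
  expect_error(pin_regression(gc), "chrom_class")
})
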