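test_that("degenerate resampling gives degenerate intervals", {
  tr <- sim_truth(n_genes = 1, seed = 2)
  sim <- simulate_counts(tr)
  ci <- bootstrap_stat(sim, stat_dnds, n_replicates = 50, seed = 1)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, ci$estimate)
  tr2 <- sim_truth(n_genes = 20, seed = 2)
  sim2 <- simulate_counts(tr2)
  ci1 <- bootstrap_stat(sim2, stat_dnds, n_replicates = 1, seed = 3)
  expect_equal(ci1$lower, ci1$upper)
  expect_equal(ci1$n_valid, 1L)
})

test_that("fixed seed reproduces intervals exactly", {
  tr <- sim_truth(n_genes = 60, seed = 4)
  sim <- simulate_counts(tr)
  a <- bootstrap_stat(sim, stat_alpha_classic, n_replicates = 200, seed = 9)
  b <- bootstrap_stat(sim, stat_alpha_classic, n_replicates = 200, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
})

test_that("interval width shrinks with more genes", {
  width <- vapply(c(40, 600), function(G) {
    tr <- sim_truth(n_genes = G, seed = 10)
    sim <- simulate_counts(tr)
    ci <- bootstrap_stat(sim, stat_pi_ratio, n_replicates = 300, seed = 11)
    ci$upper - ci$lower
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("undefined replicates are dropped and counted", {
  gc <- make_gc(pi_s = c(0.02, 0.02), pi_n = c(0.002, 0.002),
                D_n = c(0, 4))   # resamples of only gene 1 have dN = 0
  ci <- bootstrap_stat(gc, function(p) classic_alpha(p)$alpha,
                       n_replicates = 200, seed = 5, label = "alpha")
  expect_lt(ci$n_valid, ci$n_replicates)
  expect_true(all(is.finite(c(ci$lower, ci$upper))))
})

test_that("interval overlap is the significance verdict", {
  mk_ci <- function(lo, hi) structure(list(label = "alpha", estimate = (lo + hi) / 2,
                                           lower = lo, upper = hi),
                                      class = "bootstrap_ci")
  expect_true(compare_strata(mk_ci(0.1, 0.2), mk_ci(0.3, 0.4))$significant)
  expect_false(compare_strata(mk_ci(0.1, 0.3), mk_ci(0.2, 0.4))$significant)
  expect_false(compare_strata(mk_ci(0.1, 0.3), mk_ci(0.1, 0.3))$significant)
  bad <- structure(list(label = "dnds", lower = 0, upper = 1),
                   class = "bootstrap_ci")
  expect_error(compare_strata(mk_ci(0, 1), bad), "label")
})

test_that("DFE statistics refit inside replicates with a warm start", {
  tr <- sim_truth(n_genes = 150, p_adaptive = 0.4, seed = 21)
  sim <- simulate_counts(tr)
  fit <- fit_dfe(sim)
  warm <- c(fit$shape, fit$mean_S)
  ci <- bootstrap_stat(sim, function(p) stat_alpha_dfe(p, warm),
                       n_replicates = 30, seed = 2, label = "alpha_dfe")
  expect_gt(ci$n_valid, 25)
  expect_true(ci$lower < fit$alpha & fit$alpha < ci$upper)
})
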