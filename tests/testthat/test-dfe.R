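test_that("the omega identity and alpha bound hold for every fit", {
  for (seed in c(2, 3)) {
    tr <- sim_truth(n_genes = 300, p_adaptive = 0.4, seed = seed)
    fit <- fit_dfe(simulate_counts(tr))
    expect_equal(fit$omega_a + fit$omega_na, fit$dnds, tolerance = 1e-14)
    expect_lte(fit$alpha, 1)
    expect_equal(fit$alpha, fit$omega_a / fit$dnds, tolerance = 1e-14)
  }
})

test_that("moderate-size exact-model simulation recovers alpha and shape", {
  tr <- sim_truth(n_genes = 1000, gamma_shape = 0.4, gamma_mean_S = -2000,
                  p_adaptive = 0.5, seed = 23)
  fit <- fit_dfe(simulate_counts(tr))
  expect_lt(abs(fit$alpha - 0.5), 0.07)
  expect_lt(abs(fit$shape / 0.4 - 1), 0.25)
  expect_equal(fit$expected_dnds_neutral, tr$omega_na_true, tolerance = 0.15)
})

test_that("folded and unfolded fits agree on exact-model data", {
  tr <- sim_truth(n_genes = 800, p_adaptive = 0.3, seed = 29)
  sim <- simulate_counts(tr)
  ff <- fit_dfe(sim, folded = TRUE)
  fu <- fit_dfe(sim, folded = FALSE)
  expect_equal(ff$alpha, fu$alpha, tolerance = 0.03)
})

test_that("an empty nonsynonymous SFS with divergence drives alpha to the boundary", {
  tr <- sim_truth(n_genes = 200, seed = 5)
  d <- as_sfs_pair(simulate_counts(tr))
  d$sfs_n <- 0 * d$sfs_n
  fit <- fit_dfe(d)
  expect_gt(fit$alpha, 0.95)
  expect_true(fit$at_boundary)
})

test_that("degenerate inputs are rejected with clear messages", {
  tr <- sim_truth(n_genes = 50, seed = 7)
  d <- as_sfs_pair(simulate_counts(tr))
  d0 <- d; d0$sfs_s <- 0 * d0$sfs_s
  expect_error(fit_dfe(d0), "synonymous")
  d1 <- d; d1$D_s <- 0
  expect_error(fit_dfe(d1), "D_s")
  d2 <- d; d2$n_alleles <- 3
  expect_error(fit_dfe(d2), "n_alleles")
})

test_that("fit methods expose coefficients, likelihood, predictions and residuals", {
  tr <- sim_truth(n_genes = 300, seed = 11)
  fit <- fit_dfe(simulate_counts(tr))
  expect_named(coef(fit), c("shape", "mean_S", "theta", "alpha", "omega_a",
                            "omega_na"))
  expect_s3_class(logLik(fit), "logLik")
  p <- predict(fit)
  expect_equal(nrow(p), 2 * length(fit$r))
  # expected counts reproduce observed bin totals where r was profiled
  tot_obs <- with(p, tapply(observed, bin, sum))
  tot_exp <- with(p, tapply(expected, bin, sum))
  expect_equal(unname(tot_exp[-1]), unname(tot_obs[-1]), tolerance = 1e-8)
  expect_true(all(is.finite(residuals(fit))))
  expect_output(print(summary(fit)), "alpha")
})

test_that("likelihood at the truth beats perturbed parameters on average", {
  tr <- sim_truth(n_genes = 1500, gamma_shape = 0.4, gamma_mean_S = -2000,
                  p_adaptive = 0, seed = 31)
  sim <- simulate_counts(tr)
  d <- as_sfs_pair(sim)
  fit0 <- fit_dfe(d, starts = matrix(c(0.4, -2000), 1), warm_start = NULL)
  # profile log-likelihood at the truth vs strongly perturbed DFEs
  ll_at <- function(shape, meanS) {
    f <- fit_dfe(d, starts = matrix(c(shape, meanS), 1),
                 control = list(maxit = 0))
    f$loglik
  }
  expect_gt(fit0$loglik + 1e-6, ll_at(0.1, -2000))
  expect_gt(fit0$loglik + 1e-6, ll_at(2, -5))
})
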