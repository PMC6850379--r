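# Gamma-DFE fitting to paired synonymous/nonsynonymous site frequency
# spectra under the Poisson random field model, and the derived adaptive
# substitution statistics alpha, omega_a, omega_na.
#
# Likelihood: every SFS bin of both classes is an independent Poisson count.
# Synonymous bins have mean theta*L_s*r_i*nu_i (nu_i the neutral sampling
# density); nonsynonymous bins have mean theta*L_n*r_i*Hbar_i with Hbar the
# neutral density averaged over the gamma DFE. The nuisance factors r_i
# (r_1 = 1) absorb demography/ascertainment and are shared between classes,
# so the DFE is identified by the per-bin nonsynonymous:synonymous ratios.
# Given (shape, mean_S), theta and all r_i have closed-form Poisson MLEs and
# are profiled out; the numerical search is 2-D over log(shape), log(|mean_S|).

#' Fit a gamma distribution of deleterious fitness effects to SFS data
#'
#' Maximises the product of independent Poisson likelihoods over all
#' frequency classes of the synonymous and nonsynonymous spectra, with a
#' gamma DFE of deleterious effects on the nonsynonymous class and shared
#' per-class nuisance factors `r_i` (demography correction; `r_1 = 1`).
#' The expected near-neutral dN/dS under the fitted DFE,
#' `E[S/(1-e^{-S})]`, is compared with the observed `dN/dS` to give the
#' proportion of adaptive nonsynonymous substitutions
#' `alpha = 1 - E[dN/dS]/(dN/dS)`, and the per-mutation rates
#' `omega_a = alpha * dN/dS`, `omega_na = (1 - alpha) * dN/dS`.
#'
#' @param data an SFS pair as returned by [as_sfs_pair()]: a list with
#'   `sfs_s`, `sfs_n`, `L_s`, `L_n`, `D_s`, `D_n`, `n_alleles`, `folded`;
#'   or a `gene_counts`/`pooled_counts` object (pooled over all genes or the
#'   first group).
#' @param folded fit folded (minor-allele) spectra? Default `TRUE`, robust
#'   to polarisation error; unfolded input is folded on the fly. If the
#'   input spectra are already folded they cannot be unfolded.
#' @param starts matrix of optimisation starts, columns `(shape, mean_S)`;
#'   default 6 dispersed starts.
#' @param warm_start optional `c(shape, mean_S)` used as an additional
#'   (first) start — used by the bootstrap to refit quickly.
#' @param control passed to [stats::optim()] (`L-BFGS-B`).
#' @return object of class `dfe_fit`: gamma `shape` and `mean_S`, profiled
#'   `theta_hat` and nuisance vector `r`, `loglik`, convergence codes per
#'   start, `expected_dnds_neutral`, observed `dnds`, `alpha`, `omega_a`,
#'   `omega_na`, and the data.
#' @examples
#' tr <- sim_truth(n_genes = 300, seed = 1)
#' fit <- fit_dfe(simulate_counts(tr))
#' fit
#' @export
fit_dfe <- function(data, folded = TRUE, starts = NULL, warm_start = NULL,
                    control = list()) {
  if (inherits(data, c("gene_counts", "pooled_counts")))
    data <- as_sfs_pair(data)
  stopifnot(is.list(data), !is.null(data$sfs_s), !is.null(data$sfs_n))
  n <- data$n_alleles
  if (is.null(n) || n < 4) stop("n_alleles must be >= 4")
  if (sum(data$sfs_s) == 0) stop("empty synonymous SFS: theta not estimable")
  if (data$D_s <= 0) stop("D_s must be > 0 for dN/dS")

  in_folded <- isTRUE(data$folded)
  if (in_folded && !folded)
    stop("input spectra are folded; cannot fit unfolded")
  s_obs <- as.numeric(data$sfs_s)
  ns_obs <- as.numeric(data$sfs_n)
  if (folded && !in_folded) {
    s_obs <- fold_sfs(s_obs, n)
    ns_obs <- fold_sfs(ns_obs, n)
  }
  nu <- 1 / seq_len(n - 1)
  if (folded) nu <- fold_sfs(nu, n)
  sm <- prf_sampling_matrix(n)

  # coarser gamma quadrature during the search (5e-4 relative suffices for
  # locating the optimum); full precision for the reported quantities
  hbar_fun <- function(shape, mean_S, n_nodes = 64) {
    h <- dfe_hbar(shape, mean_S, n, sm = sm, n_nodes = n_nodes)
    if (folded) fold_sfs(h, n) else h
  }

  # negative log-likelihood with theta and r_i (i >= 2) profiled out
  pll <- function(par) {
    shape <- exp(par[1]); meanS <- -exp(par[2])
    h <- hbar_fun(shape, meanS)
    a <- data$L_s * nu          # synonymous relative mean
    b <- data$L_n * h           # nonsynonymous relative mean
    theta <- (s_obs[1] + ns_obs[1]) / (a[1] + b[1])
    mu_s <- numeric(length(a)); mu_n <- numeric(length(a))
    mu_s[1] <- theta * a[1]; mu_n[1] <- theta * b[1]
    if (length(a) > 1) {
      i2 <- seq.int(2, length(a))
      tot <- s_obs[i2] + ns_obs[i2]
      p <- a[i2] / (a[i2] + b[i2])
      mu_s[i2] <- tot * p
      mu_n[i2] <- tot * (1 - p)
    }
    ll <- pois_ll(s_obs, mu_s) + pois_ll(ns_obs, mu_n)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  if (is.null(starts))
    starts <- cbind(shape = c(0.2, 0.4, 1, 2, 0.5, 0.15),
                    mean_S = -c(10, 1000, 100, 1, 1e5, 1e3))
  if (!is.null(warm_start)) starts <- rbind(warm_start, starts)

  lower <- log(c(1e-3, 1e-3)); upper <- log(c(50, 1e8))
  ctl <- utils::modifyList(list(factr = 10, maxit = 500), control)
  best <- NULL; codes <- integer(0)
  for (k in seq_len(nrow(starts))) {
    p0 <- c(log(starts[k, 1]), log(-starts[k, 2]))
    fit <- tryCatch(
      stats::optim(p0, pll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) { codes <- c(codes, NA_integer_); next }
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed from all starts")

  shape <- exp(best$par[1]); mean_S <- -exp(best$par[2])
  h <- hbar_fun(shape, mean_S, n_nodes = 160)
  a <- data$L_s * nu; b <- data$L_n * h
  theta_hat <- (s_obs[1] + ns_obs[1]) / (a[1] + b[1])
  r <- (s_obs + ns_obs) / (theta_hat * (a + b))
  r[1] <- 1

  e_dnds <- dfe_omega_na(shape, mean_S)
  dnds <- (data$D_n / data$L_n) / (data$D_s / data$L_s)
  alpha <- if (data$D_n > 0) 1 - e_dnds / dnds else NA_real_
  at_boundary <- abs(best$par[2] - upper[2]) < 1e-6 ||
    abs(best$par[2] - lower[2]) < 1e-6

  out <- list(
    shape = shape, mean_S = mean_S, theta_hat = theta_hat, r = unname(r),
    loglik = -best$value, convergence = codes,
    expected_dnds_neutral = e_dnds, dnds = dnds,
    alpha = alpha,
    omega_a = if (is.na(alpha)) NA_real_ else alpha * dnds,
    omega_na = if (is.na(alpha)) NA_real_ else (1 - alpha) * dnds,
    folded = folded, n_alleles = n, at_boundary = at_boundary,
    data = list(sfs_s = s_obs, sfs_n = ns_obs, L_s = data$L_s,
                L_n = data$L_n, D_s = data$D_s, D_n = data$D_n),
    ci = NULL
  )
  class(out) <- "dfe_fit"
  out
}

pois_ll <- function(x, mu) {
  ll <- numeric(length(x))
  pos <- mu > 0
  ll[pos] <- x[pos] * log(mu[pos]) - mu[pos] - lgamma(x[pos] + 1)
  if (any(!pos & x > 0)) return(-Inf)
  sum(ll)
}

#' @export
print.dfe_fit <- function(x, digits = 4, ...) {
  cat("Gamma-DFE fit to site frequency spectra (",
      if (x$folded) "folded" else "unfolded", ", n = ", x$n_alleles, ")\n",
      sep = "")
  cat(sprintf("  shape = %.*g, mean S = %.*g, theta = %.*g/site\n",
              digits, x$shape, digits, x$mean_S, digits, x$theta_hat))
  cat(sprintf("  E[dN/dS | neutral] = %.*g, observed dN/dS = %.*g\n",
              digits, x$expected_dnds_neutral, digits, x$dnds))
  cat(sprintf("  alpha = %.*g, omega_a = %.*g, omega_na = %.*g\n",
              digits, x$alpha, digits, x$omega_a, digits, x$omega_na))
  if (x$at_boundary) cat("  note: DFE mean at optimisation boundary\n")
  invisible(x)
}

#' @method summary dfe_fit
#' @export
summary.dfe_fit <- function(object, ...) {
  out <- object
  out$r_table <- data.frame(bin = seq_along(object$r), r = object$r)
  out$expected <- stats::predict(object)
  class(out) <- "summary.dfe_fit"
  out
}

#' @export
print.summary.dfe_fit <- function(x, ...) {
  class(x) <- "dfe_fit"
  print(x)
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  nuisance r by frequency class:\n")
  print(round(x$r_table$r, 3))
  invisible(x)
}

#' @method coef dfe_fit
#' @export
coef.dfe_fit <- function(object, ...) {
  c(shape = as.numeric(object$shape), mean_S = as.numeric(object$mean_S),
    theta = as.numeric(object$theta_hat), alpha = object$alpha,
    omega_a = object$omega_a, omega_na = object$omega_na)
}

#' @method logLik dfe_fit
#' @export
logLik.dfe_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 3 + length(object$r) - 1
  class(val) <- "logLik"
  val
}

#' Expected SFS counts under a fitted DFE model
#'
#' @param object a `dfe_fit`.
#' @param ... unused.
#' @return data frame with expected and observed counts per frequency class
#'   and spectrum.
#' @method predict dfe_fit
#' @export
predict.dfe_fit <- function(object, ...) {
  n <- object$n_alleles
  nu <- 1 / seq_len(n - 1)
  h <- dfe_hbar(object$shape, object$mean_S, n)
  if (object$folded) { nu <- fold_sfs(nu, n); h <- fold_sfs(h, n) }
  mu_s <- object$theta_hat * object$data$L_s * object$r * nu
  mu_n <- object$theta_hat * object$data$L_n * object$r * h
  data.frame(bin = rep(seq_along(nu), 2),
             class = rep(c("synonymous", "nonsynonymous"), each = length(nu)),
             observed = c(object$data$sfs_s, object$data$sfs_n),
             expected = c(mu_s, mu_n))
}

#' @method fitted dfe_fit
#' @export
fitted.dfe_fit <- function(object, ...) predict(object)$expected

#' @method residuals dfe_fit
#' @export
residuals.dfe_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  p <- predict(object)
  if (type == "pearson") (p$observed - p$expected) / sqrt(pmax(p$expected, 1e-12))
  else {
    d <- 2 * (ifelse(p$observed > 0,
                     p$observed * log(p$observed / p$expected), 0) -
                (p$observed - p$expected))
    sign(p$observed - p$expected) * sqrt(pmax(d, 0))
  }
}

#' Observed versus fitted site frequency spectra
#'
#' @param x a `dfe_fit`.
#' @param ... passed to [graphics::barplot()].
#' @method plot dfe_fit
#' @export
plot.dfe_fit <- function(x, ...) {
  p <- predict(x)
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (cl in unique(p$class)) {
    q <- p[p$class == cl, ]
    bp <- graphics::barplot(q$observed, names.arg = q$bin,
                            main = paste(cl, "SFS"),
                            xlab = "frequency class", ylab = "sites", ...)
    graphics::lines(bp, q$expected, type = "b", pch = 19, col = "red3")
  }
  invisible(x)
}
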