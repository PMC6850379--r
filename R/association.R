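# Diversity-ratio summaries and the multiple regression of functional
# diversity on expression level.

#' Z-to-autosome pooled synonymous diversity ratio
#'
#' Pooled per-site synonymous diversity of Z-linked genes over that of
#' autosomal genes. At neutral equilibrium with a 1:1 sex ratio the
#' expectation is 0.75 (three Z copies per four autosomal copies);
#' background selection or a biased sex ratio pushes it lower.
#'
#' @param genes a `gene_counts` data frame.
#' @param chrom_class character vector ("Z"/"autosome") along rows; taken
#'   from a `chrom_class` column if omitted.
#' @param n_bootstrap if > 0, also bootstrap genes within each class for a
#'   percentile interval on the ratio.
#' @param seed bootstrap seed.
#' @return list with `ratio`, pooled `pi_s_Z` and `pi_s_A`, and optional
#'   `lower`/`upper`.
#' @export
diversity_ratio <- function(genes, chrom_class = genes$chrom_class,
                            n_bootstrap = 0, seed = 1L) {
  stopifnot(inherits(genes, "gene_counts"))
  if (is.null(chrom_class)) stop("chrom_class required")
  stopifnot(length(chrom_class) == nrow(genes))
  iz <- which(chrom_class == "Z"); ia <- which(chrom_class == "autosome")
  if (!length(iz) || !length(ia))
    stop("both chromosome classes must be represented")
  pz <- pool_rows(genes, iz); pa <- pool_rows(genes, ia)
  out <- list(ratio = pz$pi_s / pa$pi_s, pi_s_Z = pz$pi_s, pi_s_A = pa$pi_s)
  if (n_bootstrap > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_bootstrap), function(b) {
      z <- pool_rows(genes, sample(iz, length(iz), replace = TRUE))
      a <- pool_rows(genes, sample(ia, length(ia), replace = TRUE))
      z$pi_s / a$pi_s
    }, numeric(1))
    qs <- stats::quantile(reps[is.finite(reps)], c(0.025, 0.975), names = FALSE)
    out$lower <- qs[1]; out$upper <- qs[2]
  }
  out
}

#' Multiple regression of functional diversity on expression level
#'
#' Ordinary least squares of `log(pi_n)` on `log(pi_s)`, a chromosome-class
#' indicator, and `log(mean RPKM)` (natural logarithms). Genes with zero
#' `pi_n`, `pi_s` or RPKM are excluded (log undefined) and counted, the
#' standard treatment of zero-polymorphism genes.
#'
#' @param genes data frame with columns `pi_n`, `pi_s`, `chrom_class` and
#'   an expression column.
#' @param rpkm_col name of the expression column (default `"mean_rpkm"`).
#' @return object of class `pin_regression` wrapping the `lm` fit, with
#'   `coefficients` table, `n_genes_used`, `n_genes_dropped_zero` and
#'   residual-vs-fitted diagnostics.
#' @export
pin_regression <- function(genes, rpkm_col = "mean_rpkm") {
  stopifnot(all(c("pi_n", "pi_s", "chrom_class", rpkm_col) %in% names(genes)))
  g <- as.data.frame(genes)
  keep <- g$pi_n > 0 & g$pi_s > 0 & g[[rpkm_col]] > 0 &
    is.finite(g$pi_n) & is.finite(g$pi_s) & is.finite(g[[rpkm_col]])
  used <- g[keep, ]
  if (nrow(used) < 10) stop("fewer than 10 genes after zero exclusions")
  if (length(unique(used$chrom_class)) < 2)
    stop("rank-deficient design: chrom_class has a single level")
  d <- data.frame(log_pi_n = log(used$pi_n), log_pi_s = log(used$pi_s),
                  chrom_class = factor(used$chrom_class),
                  log_rpkm = log(used[[rpkm_col]]))
  fit <- stats::lm(log_pi_n ~ log_pi_s + chrom_class + log_rpkm, data = d)
  sm <- summary(fit)
  out <- list(
    fit = fit,
    coefficients = as.data.frame(sm$coefficients),
    n_genes_used = nrow(used),
    n_genes_dropped_zero = sum(!keep),
    diagnostics = data.frame(fitted = stats::fitted(fit),
                             residual = stats::residuals(fit)),
    r_squared = sm$r.squared
  )
  class(out) <- "pin_regression"
  out
}

#' @export
print.pin_regression <- function(x, ...) {
  cat("OLS: log(pi_n) ~ log(pi_s) + chrom_class + log(RPKM)\n")
  cat(sprintf("  %d genes used, %d dropped (zero diversity or expression); R^2 = %.3f\n",
              x$n_genes_used, x$n_genes_dropped_zero, x$r_squared))
  stats::printCoefmat(as.matrix(x$coefficients), digits = 3)
  invisible(x)
}

#' @method coef pin_regression
#' @export
coef.pin_regression <- function(object, ...) stats::coef(object$fit)

#' @method residuals pin_regression
#' @export
residuals.pin_regression <- function(object, ...) stats::residuals(object$fit)

#' @method plot pin_regression
#' @export
plot.pin_regression <- function(x, ...) {
  graphics::plot(x$diagnostics$fitted, x$diagnostics$residual,
                 xlab = "fitted", ylab = "residual",
                 main = "pin_regression diagnostics", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
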