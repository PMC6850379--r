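# Gene-level bootstrap confidence intervals for pooled statistics.

#' Bootstrap a pooled statistic by resampling genes
#'
#' Resamples genes with replacement to the original number, recomputes the
#' statistic on each replicate's pooled counts (ratio-of-sums pooling), and
#' returns 95% percentile bounds. Replicates where the statistic is
#' undefined (`NA`/`NaN`) are dropped and counted.
#'
#' @param genes a `gene_counts` data frame.
#' @param stat_fn function of one argument — a pooled-counts list as
#'   produced internally by `pool_rows()` (fields `P_n`, `P_s`, `D_n`,
#'   `D_s`, `L_n`, `L_s`, `dN`, `dS`, `pi_n`, `pi_s`, `sfs_s`, `sfs_n`,
#'   `n_alleles`, `folded`) — returning a scalar. See [stat_pi_ratio()] and
#'   friends.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer seed; fixed seed reproduces intervals exactly.
#' @param level confidence level (default 0.95, percentile bounds).
#' @param label statistic label carried on the result.
#' @return object of class `bootstrap_ci` with `estimate` (statistic on the
#'   full gene set), `lower`, `upper`, `n_replicates`, `n_valid`,
#'   `replicates`, `seed`.
#' @export
bootstrap_stat <- function(genes, stat_fn, n_replicates = 1000, seed = 1L,
                           level = 0.95, label = deparse(substitute(stat_fn))) {
  stopifnot(inherits(genes, "gene_counts"), nrow(genes) >= 1,
            n_replicates >= 1)
  G <- nrow(genes)
  est <- stat_fn(pool_rows(genes))
  set.seed(seed)
  reps <- vapply(seq_len(n_replicates), function(b) {
    idx <- sample.int(G, G, replace = TRUE)
    as.numeric(stat_fn(pool_rows(genes, idx)))
  }, numeric(1))
  valid <- reps[is.finite(reps)]
  if (!length(valid)) stop("statistic undefined in every bootstrap replicate")
  qs <- stats::quantile(valid, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  out <- list(label = label, estimate = as.numeric(est),
              lower = qs[1], upper = qs[2],
              n_replicates = n_replicates, n_valid = length(valid),
              replicates = reps, seed = seed, level = level)
  if (is.finite(est) && (est < qs[1] || est > qs[2]))
    out$flag <- "point estimate outside percentile interval"
  class(out) <- "bootstrap_ci"
  out
}

#' @export
print.bootstrap_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%s = %.*g  [%.*g, %.*g]  (%d%% percentile, %d/%d valid replicates)\n",
              x$label, digits, x$estimate, digits, x$lower, digits, x$upper,
              round(100 * x$level), x$n_valid, x$n_replicates))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Pooled statistics for use with [bootstrap_stat()]
#'
#' `stat_pi_ratio` is pooled `pi_n/pi_s`; `stat_dnds` pooled `dN/dS`;
#' `stat_alpha_classic` the classic MK alpha; `stat_alpha_dfe`,
#' `stat_omega_a` and `stat_omega_na` refit the gamma DFE on the replicate's
#' pooled spectra (pass `warm_start` from a point-estimate fit to keep 1000
#' replicates tractable; omit it to force cold multi-start fits).
#'
#' @param pooled pooled-counts list (see [bootstrap_stat()]).
#' @param warm_start optional `c(shape, mean_S)` for the DFE refits.
#' @name pooled_stats
#' @export
stat_pi_ratio <- function(pooled) pooled$pi_n / pooled$pi_s

#' @rdname pooled_stats
#' @export
stat_dnds <- function(pooled) pooled$dN / pooled$dS

#' @rdname pooled_stats
#' @export
stat_alpha_classic <- function(pooled) classic_alpha(pooled)$alpha

dfe_refit <- function(pooled, warm_start = NULL) {
  starts <- if (is.null(warm_start)) NULL else matrix(numeric(0), 0, 2)
  tryCatch(fit_dfe(pooled, warm_start = warm_start, starts = starts),
           error = function(e) NULL)
}

#' @rdname pooled_stats
#' @export
stat_alpha_dfe <- function(pooled, warm_start = NULL) {
  f <- dfe_refit(pooled, warm_start); if (is.null(f)) NA_real_ else f$alpha
}

#' @rdname pooled_stats
#' @export
stat_omega_a <- function(pooled, warm_start = NULL) {
  f <- dfe_refit(pooled, warm_start); if (is.null(f)) NA_real_ else f$omega_a
}

#' @rdname pooled_stats
#' @export
stat_omega_na <- function(pooled, warm_start = NULL) {
  f <- dfe_refit(pooled, warm_start); if (is.null(f)) NA_real_ else f$omega_na
}

#' Compare two bootstrap intervals for the same statistic
#'
#' The significance criterion is interval overlap: non-overlapping 95%
#' intervals are reported as a significant difference.
#'
#' @param ci_a,ci_b `bootstrap_ci` objects with matching labels.
#' @return list with `overlap` (logical), `significant` (logical) and a
#'   one-line `verdict`.
#' @export
compare_strata <- function(ci_a, ci_b) {
  stopifnot(inherits(ci_a, "bootstrap_ci"), inherits(ci_b, "bootstrap_ci"))
  if (!identical(ci_a$label, ci_b$label))
    stop("mismatched statistic labels: ", ci_a$label, " vs ", ci_b$label)
  overlap <- ci_a$lower <= ci_b$upper && ci_b$lower <= ci_a$upper
  list(label = ci_a$label, overlap = overlap, significant = !overlap,
       verdict = if (overlap) "intervals overlap: not significant"
                 else "intervals do not overlap: significant")
}
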