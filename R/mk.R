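# Classic McDonald-Kreitman estimate of the proportion of adaptive
# nonsynonymous substitutions.

#' Classic McDonald-Kreitman alpha
#'
#' `alpha = 1 - (dS * P_n) / (dN * P_s)`, contrasting the
#' nonsynonymous:synonymous ratio between the polymorphism and divergence
#' compartments. `alpha = 0` is the neutral null (`dN/dS = P_n/P_s`);
#' `alpha > 0` indicates positive selection, `alpha < 0` segregating
#' deleterious variation; the range is `-Inf < alpha <= 1`, with equality
#' only when `P_n = 0`. Per-gene values are noisy and often undefined —
#' pool genes (see [pool_counts()]) before estimating, as is standard.
#'
#' The two ratios must be in consistent units: when the input carries site
#' totals `L_n`/`L_s`, polymorphism is normalised per site
#' (`P_n/L_n`, `P_s/L_s`) to match the per-site `dN`, `dS` — equivalently
#' the all-raw-count form `1 - (D_s P_n)/(D_n P_s)`, since the site totals
#' cancel. Mixing per-site divergence with raw polymorphism counts would
#' shift the neutral null away from zero whenever `L_n != L_s`.
#'
#' @param counts a single pooled stratum: a `pooled_counts` row (or
#'   `gene_counts`, pooled over all rows first), the list produced by
#'   `pool_rows()`, or any list with `P_n`, `P_s`, `dN`, `dS` (and
#'   optionally `L_n`, `L_s`).
#' @param group which pooled group to use when `counts` has several.
#' @return object of class `mk_result`: `alpha`, the components used, and
#'   `reason` (non-`NA` when alpha is undefined: `P_s = 0` or `dN = 0`).
#' @examples
#' classic_alpha(list(P_n = 10, P_s = 20, dN = 0.02, dS = 0.01))  # 0.75
#' @export
classic_alpha <- function(counts, group = NULL) {
  if (inherits(counts, "gene_counts")) counts <- pool_counts(counts)
  if (inherits(counts, "pooled_counts")) {
    g <- if (is.null(group)) 1L else match(group, counts$group)
    if (is.na(g)) stop("unknown group: ", group)
    counts <- as.list(counts[g, ])
  }
  stopifnot(all(c("P_n", "P_s", "dN", "dS") %in% names(counts)))
  per_site <- !is.null(counts$L_n) && !is.null(counts$L_s)
  p_n <- if (per_site) counts$P_n / counts$L_n else counts$P_n
  p_s <- if (per_site) counts$P_s / counts$L_s else counts$P_s
  reason <- NA_character_
  if (counts$P_s == 0) reason <- "P_s = 0"
  else if (counts$dN == 0) reason <- "dN = 0"
  alpha <- if (is.na(reason))
    1 - (counts$dS * p_n) / (counts$dN * p_s)
  else NA_real_
  out <- list(alpha = alpha,
              components = counts[c("P_n", "P_s", "dN", "dS")],
              group = counts$group %||% NA_character_,
              reason = reason)
  class(out) <- "mk_result"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mk_result <- function(x, ...) {
  if (is.na(x$alpha)) {
    cat("Classic MK alpha: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Classic MK alpha = %.4f  (P_n=%g, P_s=%g, dN=%.4g, dS=%.4g)\n",
                x$alpha, x$components$P_n, x$components$P_s,
                x$components$dN, x$components$dS))
  }
  invisible(x)
}
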