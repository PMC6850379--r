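# Per-gene counts container: one row per gene with polymorphism, divergence,
# site totals, per-site diversity and derived ratios; unfolded (or folded)
# SFS matrices ride along as attributes so pooling and DFE fitting can reuse
# them without reshaping.

#' Assemble a per-gene counts table
#'
#' Builds the standard container for downstream analyses from SFS matrices
#' and divergence/site totals. `P_n`/`P_s` are SFS row sums; `pi_n`/`pi_s`
#' are per-site pairwise diversities computed from the SFS
#' (`sum_i 2 i (n-i) / (n (n-1)) * sfs_i / L`); `dN`/`dS` are per-site
#' divergences `D/L`.
#'
#' @param gene_id character vector of gene identifiers.
#' @param sfs_s,sfs_n integer matrices, genes x frequency classes.
#' @param D_s,D_n fixed synonymous/nonsynonymous differences (may be
#'   fractional when codon pathway averaging splits a codon).
#' @param L_s,L_n synonymous/nonsynonymous site counts (fractional allowed).
#' @param codons_used usable codons per gene.
#' @param n_alleles ingroup haplotype sample size.
#' @param folded are the SFS matrices folded (minor-allele) spectra?
#' @param pi_s,pi_n optional per-site diversities; computed from the SFS if
#'   omitted (only valid for unfolded or folded spectra alike, since
#'   `i(n-i)` is fold-symmetric).
#' @return data frame of class `gene_counts` with attributes `sfs_s`,
#'   `sfs_n`, `n_alleles`, `folded`.
#' @export
gene_counts_df <- function(gene_id, sfs_s, sfs_n, D_s, D_n, L_s, L_n,
                           codons_used, n_alleles, folded = FALSE,
                           pi_s = NULL, pi_n = NULL) {
  sfs_s <- as.matrix(sfs_s); sfs_n <- as.matrix(sfs_n)
  if (is.null(pi_s)) pi_s <- sfs_pi(sfs_s, n_alleles, folded) / L_s
  if (is.null(pi_n)) pi_n <- sfs_pi(sfs_n, n_alleles, folded) / L_n
  df <- data.frame(
    gene_id = gene_id,
    P_n = rowSums(sfs_n), P_s = rowSums(sfs_s),
    D_n = D_n, D_s = D_s, L_n = L_n, L_s = L_s,
    dN = D_n / L_n, dS = D_s / L_s,
    pi_n = pi_n, pi_s = pi_s,
    codons_used = codons_used,
    stringsAsFactors = FALSE
  )
  attr(df, "sfs_s") <- sfs_s
  attr(df, "sfs_n") <- sfs_n
  attr(df, "n_alleles") <- as.integer(n_alleles)
  attr(df, "folded") <- isTRUE(folded)
  class(df) <- c("gene_counts", "data.frame")
  df
}

# Total pairwise heterozygosity implied by an SFS matrix (per gene, not per
# site): sum_i sfs_i * 2 i (n-i) / (n (n-1)). Works folded or unfolded
# because the weight is symmetric in i <-> n-i.
sfs_pi <- function(sfs, n_alleles, folded = FALSE) {
  n <- n_alleles
  i <- seq_len(ncol(sfs))
  w <- 2 * i * (n - i) / (n * (n - 1))
  drop(sfs %*% w)
}

#' Pool per-gene counts into strata
#'
#' Element-wise sums of counts, sites and SFS within each group, with ratio
#' statistics recomputed from the pooled sums (ratio-of-sums, never
#' mean-of-ratios): pooled `dN = sum(D_n)/sum(L_n)`, pooled
#' `pi = sum(pi_g L_g)/sum(L_g)`.
#'
#' @param gc a `gene_counts` data frame.
#' @param grouping factor/character vector along rows of `gc`, or `NULL` to
#'   pool everything into one stratum named "all".
#' @return data frame of class `pooled_counts`, one row per group, with
#'   pooled SFS matrices (group x frequency class) in attributes.
#' @export
pool_counts <- function(gc, grouping = NULL) {
  stopifnot(inherits(gc, "gene_counts"))
  if (is.null(grouping)) grouping <- rep("all", nrow(gc))
  stopifnot(length(grouping) == nrow(gc))
  grouping <- factor(grouping)
  if (any(tapply(rep(1, nrow(gc)), grouping, length) == 0))
    warning("empty group(s) in pooling")
  sfs_s <- attr(gc, "sfs_s"); sfs_n <- attr(gc, "sfs_n")
  agg <- function(v) as.numeric(tapply(v, grouping, sum))
  out <- data.frame(
    group = levels(grouping),
    n_genes = as.integer(table(grouping)),
    P_n = agg(gc$P_n), P_s = agg(gc$P_s),
    D_n = agg(gc$D_n), D_s = agg(gc$D_s),
    L_n = agg(gc$L_n), L_s = agg(gc$L_s),
    codons_used = agg(gc$codons_used),
    stringsAsFactors = FALSE
  )
  out$dN <- out$D_n / out$L_n
  out$dS <- out$D_s / out$L_s
  out$pi_n <- agg(gc$pi_n * gc$L_n) / out$L_n
  out$pi_s <- agg(gc$pi_s * gc$L_s) / out$L_s
  ps <- rowsum(sfs_s, grouping); pn <- rowsum(sfs_n, grouping)
  attr(out, "sfs_s") <- ps[levels(grouping), , drop = FALSE]
  attr(out, "sfs_n") <- pn[levels(grouping), , drop = FALSE]
  attr(out, "n_alleles") <- attr(gc, "n_alleles")
  attr(out, "folded") <- attr(gc, "folded")
  class(out) <- c("pooled_counts", "data.frame")
  out
}

# Fast pooled summary of a row subset (used heavily by the bootstrap):
# returns a plain list with pooled counts, sites, ratios and SFS vectors.
pool_rows <- function(gc, idx = seq_len(nrow(gc))) {
  sfs_s <- attr(gc, "sfs_s"); sfs_n <- attr(gc, "sfs_n")
  L_n <- sum(gc$L_n[idx]); L_s <- sum(gc$L_s[idx])
  D_n <- sum(gc$D_n[idx]); D_s <- sum(gc$D_s[idx])
  list(
    P_n = sum(gc$P_n[idx]), P_s = sum(gc$P_s[idx]),
    D_n = D_n, D_s = D_s, L_n = L_n, L_s = L_s,
    dN = D_n / L_n, dS = D_s / L_s,
    pi_n = sum(gc$pi_n[idx] * gc$L_n[idx]) / L_n,
    pi_s = sum(gc$pi_s[idx] * gc$L_s[idx]) / L_s,
    sfs_s = colSums(sfs_s[idx, , drop = FALSE]),
    sfs_n = colSums(sfs_n[idx, , drop = FALSE]),
    n_alleles = attr(gc, "n_alleles"),
    folded = attr(gc, "folded"),
    n_genes = length(idx)
  )
}

#' Extract a pooled SFS pair for DFE fitting
#'
#' @param x a `pooled_counts` data frame (or `gene_counts`, pooled first).
#' @param group which pooled stratum to extract (default first).
#' @return list with `sfs_s`, `sfs_n`, `L_s`, `L_n`, `D_s`, `D_n`,
#'   `n_alleles`, `folded` — the input contract of [fit_dfe()].
#' @export
as_sfs_pair <- function(x, group = NULL) {
  if (inherits(x, "gene_counts")) x <- pool_counts(x)
  stopifnot(inherits(x, "pooled_counts"))
  g <- if (is.null(group)) 1L else match(group, x$group)
  if (is.na(g)) stop("unknown group: ", group)
  list(sfs_s = attr(x, "sfs_s")[g, ], sfs_n = attr(x, "sfs_n")[g, ],
       L_s = x$L_s[g], L_n = x$L_n[g], D_s = x$D_s[g], D_n = x$D_n[g],
       n_alleles = attr(x, "n_alleles"), folded = attr(x, "folded"))
}

#' @export
print.gene_counts <- function(x, ...) {
  cat(sprintf("Per-gene counts: %d genes, n = %d haplotypes (%s SFS)\n",
              nrow(x), attr(x, "n_alleles"),
              if (attr(x, "folded")) "folded" else "unfolded"))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more genes\n")
  invisible(x)
}
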