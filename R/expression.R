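# Expression-level computation and sex-/tissue-bias classification.

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = N_c * 1e9 / (N_tot * L_c)` with `N_c` the reads mapped to the
#' gene, `N_tot` the total mapped reads in the sample and `L_c` the gene
#' length in bp.
#'
#' @param counts vector or gene x sample matrix of read counts.
#' @param gene_lengths gene lengths in bp, recycled along rows.
#' @return RPKM values with the shape of `counts`.
#' @examples
#' rpkm(10, 1000)        # with a library of 1e6 reads implied by the input:
#' rpkm(c(10), 1000)     # N_tot is the column sum, so a one-gene library
#' @export
rpkm <- function(counts, gene_lengths) {
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (is.matrix(counts)) {
    n_tot <- colSums(counts)
    if (any(n_tot <= 0)) stop("zero library size")
    sweep(counts / gene_lengths, 2, n_tot, `/`) * 1e9
  } else {
    n_tot <- sum(counts)
    if (n_tot <= 0) stop("zero library size")
    counts * 1e9 / (n_tot * gene_lengths)
  }
}

#' Classify genes as female-, male- or unbiased from RPKM ratios
#'
#' A gene with `rpkm_f / rpkm_m > 1.5` is female biased, `< 0.66` male
#' biased, otherwise (including exactly 1.5 or 0.66) unbiased. A gene
#' expressed only in females (`rpkm_m = 0`, `rpkm_f > 0`) has infinite
#' ratio and is female biased; a gene with both means zero is unbiased and
#' flagged unexpressed.
#'
#' @param rpkm_f,rpkm_m mean RPKM across female and male samples (>= 0).
#' @return character vector in `{"female","male","unbiased"}` with
#'   attribute `unexpressed` (logical vector).
#' @export
classify_sex_bias <- function(rpkm_f, rpkm_m) {
  if (any(rpkm_f < 0) || any(rpkm_m < 0)) stop("RPKM must be nonnegative")
  ratio <- ifelse(rpkm_m == 0, ifelse(rpkm_f > 0, Inf, NaN), rpkm_f / rpkm_m)
  bias <- ifelse(is.nan(ratio), "unbiased",
                 ifelse(ratio > 1.5, "female",
                        ifelse(ratio < 0.66, "male", "unbiased")))
  attr(bias, "unexpressed") <- rpkm_f == 0 & rpkm_m == 0
  bias
}

#' Classify genes as ovary- or gut-biased from a differential-expression table
#'
#' Thresholds an externally produced DE result table (ovary vs gut
#' contrast): adjusted p below `fdr_threshold` and `log2FC > lfc_threshold`
#' is ovary biased; adjusted p below threshold and `log2FC < -lfc_threshold`
#' is gut biased; anything else is "none". Genes with missing adjusted p are
#' skipped with a warning.
#'
#' @param de_table data frame with columns `gene_id`, `log2FC`, `padj`.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1.5).
#' @return named character vector (`gene_id` -> `{"ovary","gut","none"}`).
#' @export
classify_tissue_bias <- function(de_table, fdr_threshold = 0.05,
                                 lfc_threshold = 1.5) {
  stopifnot(all(c("gene_id", "log2FC", "padj") %in% names(de_table)))
  miss <- is.na(de_table$padj)
  if (any(miss)) {
    warning(sum(miss), " gene(s) with missing adjusted p skipped")
    de_table <- de_table[!miss, ]
  }
  sig <- de_table$padj < fdr_threshold
  bias <- ifelse(sig & de_table$log2FC > lfc_threshold, "ovary",
                 ifelse(sig & de_table$log2FC < -lfc_threshold, "gut", "none"))
  stats::setNames(bias, de_table$gene_id)
}

#' Chi-square enrichment test on a 2x2 contingency table
#'
#' Pearson chi-square (without continuity correction) for association
#' between, e.g., chromosome class and tissue-bias category.
#'
#' @param table nonnegative integer 2x2 matrix.
#' @return `htest` object from [stats::chisq.test()]; warns when any
#'   expected count is below 5.
#' @export
enrichment_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5; chi-square approximation is poor")
  ht
}

#' Annotate genes with expression level and sex-bias category
#'
#' Computes per-sample RPKM, averages within each sex, and applies
#' [classify_sex_bias()].
#'
#' @param counts gene x sample count matrix (rownames = gene ids).
#' @param samples data frame with `sample_id` and `sex` covering all
#'   columns of `counts`.
#' @param gene_lengths bp per gene, aligned with rows.
#' @param tissue_bias optional named vector from [classify_tissue_bias()].
#' @return data frame of class `gene_annot`: `gene_id`, `rpkm_f`, `rpkm_m`,
#'   `mean_rpkm`, `bias`, `tissue_bias`, `unexpressed`.
#' @export
annotate_genes <- function(counts, samples, gene_lengths, tissue_bias = NULL) {
  stopifnot(ncol(counts) == nrow(samples),
            all(colnames(counts) %in% samples$sample_id))
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  r <- rpkm(counts, gene_lengths)
  rpkm_f <- rowMeans(r[, samples$sex == "female", drop = FALSE])
  rpkm_m <- rowMeans(r[, samples$sex == "male", drop = FALSE])
  bias <- classify_sex_bias(rpkm_f, rpkm_m)
  out <- data.frame(
    gene_id = rownames(counts),
    rpkm_f = rpkm_f, rpkm_m = rpkm_m,
    mean_rpkm = rowMeans(r),
    bias = as.character(bias),
    tissue_bias = if (is.null(tissue_bias)) "none"
      else unname(tissue_bias[rownames(counts)]),
    unexpressed = attr(bias, "unexpressed"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$tissue_bias[is.na(out$tissue_bias)] <- "none"
  class(out) <- c("gene_annot", "data.frame")
  out
}
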