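# Synthetic-data generator: per-gene polymorphism/divergence counts drawn
# from the same Poisson-random-field family the DFE fitter assumes, plus a
# sex-biased negative-binomial expression matrix. Ground truth is recorded
# on every output so recovery tests are exact-model tests.

#' Ground-truth parameter set for the synthetic-data generator
#'
#' Defaults describe a large-Ne butterfly-like population: synonymous
#' diversity ~0.027/site, a leptokurtic gamma DFE (shape 0.4, mean
#' population-scaled effect -2000), 60% adaptive nonsynonymous
#' substitutions, synonymous divergence 0.162/site, and the neutral
#' three-quarters Z-to-autosome effective-size ratio expected at a 1:1
#' sex ratio.
#'
#' @param n_genes number of genes to simulate.
#' @param n_alleles ingroup haplotype sample size (e.g. 20 for 10 diploids).
#' @param theta_s population-scaled synonymous mutation rate per site.
#' @param gamma_shape shape of the gamma DFE of deleterious effects.
#' @param gamma_mean_S mean population-scaled selection coefficient of
#'   deleterious nonsynonymous mutations (<= 0; 0 = all neutral).
#' @param p_adaptive fraction of nonsynonymous substitutions that are
#'   adaptive, in [0, 1).
#' @param ne_ratio_Z Z-to-autosome effective-size ratio in (0, 1], applied
#'   to polymorphism only.
#' @param div_s expected synonymous divergence per site.
#' @param frac_z fraction of genes on the Z chromosome.
#' @param div_mult_z optional Z divergence multiplier (male-biased mutation),
#'   default 1.
#' @param mean_codons mean gene length in codons (lognormal across genes).
#' @param seed integer random seed.
#' @return object of class `sim_truth` (a validated list, with derived
#'   `omega_na_true` and `omega_a_true` attached).
#' @export
sim_truth <- function(n_genes = 1000, n_alleles = 20, theta_s = 0.027,
                      gamma_shape = 0.4, gamma_mean_S = -2000,
                      p_adaptive = 0.6, ne_ratio_Z = 0.75, div_s = 0.162,
                      frac_z = 0.5, div_mult_z = 1, mean_codons = 450,
                      seed = 1L) {
  truth <- list(n_genes = n_genes, n_alleles = n_alleles, theta_s = theta_s,
                gamma_shape = gamma_shape, gamma_mean_S = gamma_mean_S,
                p_adaptive = p_adaptive, ne_ratio_Z = ne_ratio_Z,
                div_s = div_s, frac_z = frac_z, div_mult_z = div_mult_z,
                mean_codons = mean_codons, seed = as.integer(seed))
  validate_truth(truth)
  truth$omega_na_true <- dfe_omega_na(truth$gamma_shape, truth$gamma_mean_S)
  truth$omega_a_true <- truth$p_adaptive / (1 - truth$p_adaptive) *
    truth$omega_na_true
  class(truth) <- "sim_truth"
  truth
}

validate_truth <- function(truth) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid `", field, "`: ", what, call. = FALSE)
  }
  chk(truth$n_genes >= 1, "n_genes", "must be >= 1")
  chk(truth$n_alleles >= 4, "n_alleles", "must be >= 4")
  chk(is.finite(truth$theta_s) && truth$theta_s > 0, "theta_s", "must be > 0")
  chk(truth$gamma_shape > 0, "gamma_shape", "must be > 0")
  chk(truth$gamma_mean_S <= 0, "gamma_mean_S", "must be <= 0")
  chk(truth$p_adaptive >= 0 && truth$p_adaptive < 1, "p_adaptive",
      "must be in [0, 1)")
  chk(truth$ne_ratio_Z > 0 && truth$ne_ratio_Z <= 1, "ne_ratio_Z",
      "must be in (0, 1]")
  chk(truth$div_s > 0, "div_s", "must be > 0")
  chk(truth$frac_z >= 0 && truth$frac_z <= 1, "frac_z", "must be in [0, 1]")
  chk(truth$div_mult_z > 0, "div_mult_z", "must be > 0")
  chk(truth$mean_codons >= 30, "mean_codons", "must be >= 30")
  invisible(truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Ground truth for synthetic fast-Z data\n")
  cat(sprintf("  %d genes (frac Z = %.2f), n = %d haplotypes, seed %d\n",
              x$n_genes, x$frac_z, x$n_alleles, x$seed))
  cat(sprintf("  theta_s = %g/site, div_s = %g/site, Ne(Z)/Ne(A) = %g\n",
              x$theta_s, x$div_s, x$ne_ratio_Z))
  cat(sprintf("  DFE: gamma(shape = %g, mean S = %g); p_adaptive = %g\n",
              x$gamma_shape, x$gamma_mean_S, x$p_adaptive))
  cat(sprintf("  implied omega_na = %.4f, omega_a = %.4f, dN/dS = %.4f\n",
              x$omega_na_true, x$omega_a_true,
              x$omega_na_true + x$omega_a_true))
  invisible(x)
}

#' Simulate per-gene polymorphism and divergence counts
#'
#' Draws, for each gene, unfolded synonymous and nonsynonymous site
#' frequency spectra and fixed synonymous/nonsynonymous divergence counts
#' from Poisson-random-field expectations: the synonymous class at derived
#' count i has Poisson mean `theta_s * L_s / i`; the nonsynonymous class
#' integrates the sampling density over the gamma DFE. Divergence means are
#' `L_s * div_s` and `L_n * div_s * (omega_na + omega_a)`. Z-linked genes
#' have their polymorphism scaled by `ne_ratio_Z` (divergence is
#' Ne-independent for neutral sites and is left unscaled apart from the
#' optional `div_mult_z`). Adaptive substitutions contribute to divergence
#' only, the standard McDonald-Kreitman assumption.
#'
#' @param truth a [sim_truth()] object.
#' @return a `gene_counts` data frame (see [gene_counts_df()]) with one row
#'   per gene, unfolded SFS matrices in attributes `sfs_s`/`sfs_n`,
#'   `n_alleles`, and the generating `sim_truth` in attribute `truth`;
#'   extra columns `true_bias` (latent expression-bias label) and
#'   `chrom_class`.
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_truth(truth)
  set.seed(truth$seed)
  G <- truth$n_genes
  n <- truth$n_alleles
  i <- seq_len(n - 1)

  hbar_n <- dfe_hbar(truth$gamma_shape, truth$gamma_mean_S, n)
  hbar_s <- 1 / i
  omega_tot <- truth$omega_na_true + truth$omega_a_true

  n_z <- round(G * truth$frac_z)
  chrom <- sample(rep(c("Z", "autosome"), c(n_z, G - n_z)))
  codons <- pmax(50L, round(stats::rlnorm(G, log(truth$mean_codons), 0.35)))
  L_tot <- 3 * codons
  L_s <- L_tot * 0.25
  L_n <- L_tot * 0.75
  pol_scale <- ifelse(chrom == "Z", truth$ne_ratio_Z, 1)
  div_scale <- ifelse(chrom == "Z", truth$div_mult_z, 1)

  sfs_s <- matrix(stats::rpois(G * (n - 1),
                               outer(truth$theta_s * L_s * pol_scale, hbar_s)),
                  nrow = G)
  sfs_n <- matrix(stats::rpois(G * (n - 1),
                               outer(truth$theta_s * L_n * pol_scale, hbar_n)),
                  nrow = G)
  D_s <- stats::rpois(G, L_s * truth$div_s * div_scale)
  D_n <- stats::rpois(G, L_n * truth$div_s * div_scale * omega_tot)
  true_bias <- sample(c("female", "male", "unbiased"), G, replace = TRUE,
                      prob = c(0.15, 0.15, 0.70))

  gc <- gene_counts_df(
    gene_id = sprintf("g%05d", seq_len(G)),
    sfs_s = sfs_s, sfs_n = sfs_n, D_s = D_s, D_n = D_n,
    L_s = L_s, L_n = L_n, codons_used = codons, n_alleles = n
  )
  gc$chrom_class <- chrom
  gc$true_bias <- true_bias
  attr(gc, "truth") <- truth
  class(gc) <- c("sim_counts", class(gc))
  gc
}

#' Simulate a sex-biased expression count matrix
#'
#' Negative-binomial read counts for the simulated genes across
#' `n_samples_per_sex` whole-abdomen samples per sex, with varying library
#' sizes. Genes whose latent `true_bias` label is "female" have female-sample
#' expected expression multiplied by `bias_fold`; "male" genes are mirrored.
#'
#' @param sim output of [simulate_counts()] (provides gene ids, lengths and
#'   latent bias labels).
#' @param n_samples_per_sex samples per sex (>= 2).
#' @param bias_fold expression fold-change of biased genes (>= 1; 1 = no
#'   signal).
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @param mean_depth expected reads per sample before library-size jitter.
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (data frame: sample_id, sex, tissue, treatment), `gene_lengths`, and
#'   `true_bias`.
#' @export
simulate_expression <- function(sim, n_samples_per_sex = 5, bias_fold = 4,
                                dispersion = 0.05, mean_depth = 2e7) {
  stopifnot(inherits(sim, "sim_counts"))
  if (n_samples_per_sex < 2) stop("n_samples_per_sex must be >= 2")
  if (bias_fold < 1) stop("invalid `bias_fold`: must be >= 1")
  truth <- attr(sim, "truth")
  set.seed(truth$seed + 1L)
  G <- nrow(sim)
  ns <- 2L * n_samples_per_sex
  sex <- rep(c("female", "male"), each = n_samples_per_sex)
  sample_id <- sprintf("%s_%d", substr(sex, 1, 1), rep(seq_len(n_samples_per_sex), 2))
  lens <- 3 * sim$codons_used

  base <- stats::rlnorm(G, meanlog = 3, sdlog = 1.2)       # latent RPKM-like level
  # female-biased genes have female means scaled up by bias_fold; male-biased
  # genes are the mirror image (male means up, i.e. female means down)
  fold_f <- ifelse(sim$true_bias == "female", bias_fold,
                   ifelse(sim$true_bias == "male", 1 / bias_fold, 1))
  lib <- stats::runif(ns, 0.6, 1.4) * mean_depth
  mu <- outer(base * lens / 1e3, rep(1, ns))   # counts at 1M reads
  mu[, sex == "female"] <- mu[, sex == "female"] * fold_f
  mu <- sweep(mu, 2, lib / 1e6, `*`)
  counts <- matrix(stats::rnbinom(G * ns, mu = mu, size = 1 / dispersion),
                   nrow = G, dimnames = list(sim$gene_id, sample_id))
  samples <- data.frame(sample_id = sample_id, sex = sex,
                        tissue = "abdomen", treatment = "adult",
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples,
       gene_lengths = stats::setNames(lens, sim$gene_id),
       true_bias = stats::setNames(sim$true_bias, sim$gene_id))
}

#' Write simulated data to a directory of plain-text files
#'
#' Writes `genes.tsv` (per-gene metadata and ground truth), `counts.tsv`,
#' `samples.tsv`, `truth.tsv` and the per-gene FASTA alignments produced by
#' [emit_alignments()].
#'
#' @param sim output of [simulate_counts()].
#' @param dir output directory (created if missing).
#' @param expression optional output of [simulate_expression()].
#' @param alignments write per-gene FASTA alignments too? (slower)
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = NULL, alignments = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(sim, "truth")
  genes <- as.data.frame(sim)
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- truth[!vapply(truth, is.null, logical(1))]
  utils::write.table(data.frame(field = names(tr),
                                value = vapply(tr, as.character, character(1))),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sfs_tsv(sim, dir)
  if (!is.null(expression)) {
    cnt <- data.frame(gene_id = rownames(expression$counts),
                      expression$counts, check.names = FALSE)
    utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expression$samples, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (alignments) emit_alignments(sim, dir = file.path(dir, "alignments"))
  invisible(dir)
}

write_sfs_tsv <- function(gc, dir) {
  for (cls in c("sfs_s", "sfs_n")) {
    m <- attr(gc, cls)
    df <- data.frame(gene_id = gc$gene_id, m, check.names = FALSE)
    names(df)[-1] <- paste0("f", seq_len(ncol(m)))
    utils::write.table(df, file.path(dir, paste0(cls, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
}
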