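# End-to-end orchestration: counts -> expression classification ->
# stratified MK/DFE statistics with gene-bootstrap intervals -> report
# tables shaped like the standard fast-Z summary (statistic x linkage x
# bias-category grid, plus a synonymous-diversity table and the
# diversity-on-expression regression).

#' Build a pipeline run configuration
#'
#' @param mode "simulate" (generate data from `truth`) or "real" (read the
#'   file paths below).
#' @param out_dir output directory for all result tables.
#' @param truth list of [sim_truth()] arguments (simulate mode).
#' @param alignments_dir directory of per-gene FASTA alignments (real mode).
#' @param genes_file TSV with `gene_id` and `chrom_class` (real mode).
#' @param counts_file,samples_file expression count matrix TSV (first column
#'   `gene_id`) and sample sheet TSV (`sample_id`, `sex`, ...).
#' @param de_file optional DE table TSV (`gene_id`, `log2FC`, `padj`).
#' @param gene_lengths_col column of `genes_file` holding gene length in bp
#'   (real mode; default "length").
#' @param n_bootstrap bootstrap replicates per stratum (default 1000).
#' @param folded fit folded spectra in the DFE model?
#' @param seed integer seed recorded in every output.
#' @param n_samples_per_sex,bias_fold expression-simulation settings
#'   (simulate mode).
#' @param use_alignments in simulate mode, emit FASTA alignments and recount
#'   them through the codon machinery instead of using the simulator's
#'   bookkeeping directly (slower; exercises the full chain).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "real"), out_dir,
                       truth = list(), alignments_dir = NULL,
                       genes_file = NULL, counts_file = NULL,
                       samples_file = NULL, de_file = NULL,
                       gene_lengths_col = "length",
                       n_bootstrap = 1000, folded = TRUE, seed = 1L,
                       n_samples_per_sex = 5, bias_fold = 4,
                       use_alignments = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, truth = truth,
              alignments_dir = alignments_dir, genes_file = genes_file,
              counts_file = counts_file, samples_file = samples_file,
              de_file = de_file, gene_lengths_col = gene_lengths_col,
              n_bootstrap = n_bootstrap, folded = folded,
              seed = as.integer(seed),
              n_samples_per_sex = n_samples_per_sex, bias_fold = bias_fold,
              use_alignments = use_alignments)
  if (mode == "real") {
    for (f in c("alignments_dir", "genes_file", "counts_file", "samples_file")) {
      if (is.null(cfg[[f]])) stop("real mode requires `", f, "`")
      if (!file.exists(cfg[[f]])) stop("missing path for `", f, "`: ", cfg[[f]])
    }
    if (!is.null(cfg$de_file) && !file.exists(cfg$de_file))
      stop("missing path for `de_file`: ", cfg$de_file)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat YAML file
#'
#' @param path YAML file whose keys mirror [run_config()] arguments
#'   (`truth.*` keys are collected into the truth list).
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y[grepl("^truth\\.", names(y))]
  names(tr) <- sub("^truth\\.", "", names(tr))
  y <- y[!grepl("^truth\\.", names(y))]
  y$truth <- c(tr, y$truth)
  do.call(run_config, y)
}

#' Run the full fast-Z analysis pipeline
#'
#' Executes counting (or simulation), expression classification,
#' stratification by chromosome class and sex-bias category, classic MK and
#' gamma-DFE estimation, gene-bootstrap intervals, the diversity-ratio
#' summary and the diversity-on-expression regression, and writes all
#' result tables to `config$out_dir`. Re-running with the same config and
#' seed reproduces every table byte-identically.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `genes` (annotated `gene_counts`),
#'   `strata` (per-stratum statistics with CIs), `master` (the wide report
#'   table), `table_pi_s`, `diversity_ratio`, `regression`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("fastz %s | R %s", as.character(utils::packageVersion("fastz")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("mode=%s seed=%d n_bootstrap=%d folded=%s",
                         config$mode, config$seed, config$n_bootstrap, config$folded))

  if (config$mode == "simulate") {
    truth <- do.call(sim_truth, utils::modifyList(config$truth,
                                                  list(seed = config$seed)))
    sim <- simulate_counts(truth)
    if (config$use_alignments) {
      alns <- emit_alignments(sim)
      gc <- gene_counts_from_alignments(alns)
      gc$chrom_class <- sim$chrom_class
      gc$true_bias <- sim$true_bias
      attr(gc, "truth") <- truth
      class(gc) <- c("sim_counts", class(gc))
    } else gc <- sim
    expr <- simulate_expression(sim, config$n_samples_per_sex,
                                config$bias_fold)
    counts <- expr$counts; samples <- expr$samples
    gene_lengths <- expr$gene_lengths
    de_table <- NULL
    log_lines <- c(log_lines, sprintf("simulated %d genes", nrow(gc)))
  } else {
    gc <- gene_counts_from_alignments(config$alignments_dir)
    meta <- utils::read.delim(config$genes_file, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "chrom_class") %in% names(meta)))
      stop("genes_file must have gene_id and chrom_class columns")
    gc$chrom_class <- meta$chrom_class[match(gc$gene_id, meta$gene_id)]
    counts <- utils::read.delim(config$counts_file, check.names = FALSE)
    rn <- counts[[1]]; counts <- as.matrix(counts[-1]); rownames(counts) <- rn
    samples <- utils::read.delim(config$samples_file, stringsAsFactors = FALSE)
    gene_lengths <- stats::setNames(
      if (config$gene_lengths_col %in% names(meta))
        meta[[config$gene_lengths_col]] else 3 * gc$codons_used[match(meta$gene_id, gc$gene_id)],
      meta$gene_id)[rownames(counts)]
    de_table <- if (!is.null(config$de_file))
      utils::read.delim(config$de_file, stringsAsFactors = FALSE) else NULL
  }

  tissue <- if (!is.null(de_table)) classify_tissue_bias(de_table) else NULL
  annot <- annotate_genes(counts, samples, gene_lengths, tissue)
  gc$bias <- annot$bias[match(gc$gene_id, annot$gene_id)]
  gc$mean_rpkm <- annot$mean_rpkm[match(gc$gene_id, annot$gene_id)]
  gc$bias[is.na(gc$bias)] <- "unbiased"

  strata <- stratum_table(gc, config)
  master <- master_table(strata)
  dr <- tryCatch(
    diversity_ratio(gc, n_bootstrap = config$n_bootstrap, seed = config$seed),
    error = function(e) { log_lines <<- c(log_lines, paste("diversity_ratio:", conditionMessage(e))); NULL })
  tab2 <- pi_s_table(strata, dr)
  reg <- tryCatch(pin_regression(gc),
                  error = function(e) { log_lines <<- c(log_lines, paste("regression:", conditionMessage(e))); NULL })
  if (!is.null(reg))
    log_lines <- c(log_lines, sprintf("regression: %d genes used, %d dropped (zero)",
                                      reg$n_genes_used, reg$n_genes_dropped_zero))

  wt <- function(df, f) utils::write.table(df, file.path(config$out_dir, f),
                                           sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(gc), "gene_counts.tsv")
  write_sfs_tsv(gc, config$out_dir)
  wt(annot, "annot.tsv")
  wt(strata$ci, "ci.tsv")
  wt(strata$mk, "mk_classic.tsv")
  wt(strata$dfe, "dfe_fits.tsv")
  wt(master, "master_table.tsv")
  wt(tab2, "table2.tsv")
  if (!is.null(reg)) {
    wt(data.frame(term = rownames(reg$coefficients), reg$coefficients,
                  check.names = FALSE), "regression.tsv")
    wt(reg$diagnostics, "diagnostics.tsv")
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(genes = gc, strata = strata, master = master,
                 table_pi_s = tab2, diversity_ratio = dr, regression = reg,
                 config = config))
}

# All eight strata (chromosome class x {All, female, male, unbiased}), each
# with pooled statistics, a DFE fit, and one shared bootstrap loop per
# stratum computing every statistic on the same replicates.
stratum_table <- function(gc, config) {
  classes <- c("autosome", "Z")
  cats <- c("All", "female", "male", "unbiased")
  ci_rows <- list(); mk_rows <- list(); dfe_rows <- list()
  for (cl in classes) for (ct in cats) {
    idx <- which(gc$chrom_class == cl & (ct == "All" | gc$bias == ct))
    label <- paste(cl, ct, sep = ".")
    if (!length(idx)) {
      ci_rows[[label]] <- data.frame(stratum = label, statistic = stat_names(),
                                     estimate = NA_real_, lower = NA_real_,
                                     upper = NA_real_, n_valid = 0L,
                                     n_genes = 0L)
      next
    }
    sub <- gc[idx, , drop = FALSE]
    attr(sub, "sfs_s") <- attr(gc, "sfs_s")[idx, , drop = FALSE]
    attr(sub, "sfs_n") <- attr(gc, "sfs_n")[idx, , drop = FALSE]
    attr(sub, "n_alleles") <- attr(gc, "n_alleles")
    attr(sub, "folded") <- attr(gc, "folded")
    class(sub) <- c("gene_counts", "data.frame")
    res <- stratum_stats(sub, config$n_bootstrap, config$seed, config$folded)
    ci_rows[[label]] <- data.frame(stratum = label, statistic = stat_names(),
                                   estimate = res$est, lower = res$lower,
                                   upper = res$upper, n_valid = res$n_valid,
                                   n_genes = length(idx))
    mk_rows[[label]] <- data.frame(stratum = label, alpha = res$est["alpha_classic"],
                                   t(unlist(res$mk$components)), row.names = NULL)
    if (!is.null(res$fit))
      dfe_rows[[label]] <- data.frame(stratum = label, shape = res$fit$shape,
                                      mean_S = res$fit$mean_S,
                                      theta_hat = res$fit$theta_hat,
                                      loglik = res$fit$loglik,
                                      expected_dnds_neutral = res$fit$expected_dnds_neutral,
                                      alpha = res$fit$alpha,
                                      omega_a = res$fit$omega_a,
                                      omega_na = res$fit$omega_na)
  }
  list(ci = do.call(rbind, c(ci_rows, make.row.names = FALSE)),
       mk = do.call(rbind, c(mk_rows, make.row.names = FALSE)),
       dfe = do.call(rbind, c(dfe_rows, make.row.names = FALSE)))
}

stat_names <- function() c("pi_n_pi_s", "dnds", "alpha_classic",
                           "alpha_dfe", "omega_a", "omega_na", "pi_s")

stratum_stats <- function(sub, n_boot, seed, folded) {
  pooled <- pool_rows(sub)
  fit <- tryCatch(fit_dfe(pooled, folded = folded), error = function(e) NULL)
  mk <- classic_alpha(pooled)
  warm <- if (is.null(fit)) NULL else c(fit$shape, fit$mean_S)
  est <- c(pi_n_pi_s = pooled$pi_n / pooled$pi_s,
           dnds = pooled$dN / pooled$dS,
           alpha_classic = mk$alpha,
           alpha_dfe = if (is.null(fit)) NA_real_ else fit$alpha,
           omega_a = if (is.null(fit)) NA_real_ else fit$omega_a,
           omega_na = if (is.null(fit)) NA_real_ else fit$omega_na,
           pi_s = pooled$pi_s)
  G <- nrow(sub)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 7, dimnames = list(NULL, stat_names()))
  for (b in seq_len(n_boot)) {
    p <- pool_rows(sub, sample.int(G, G, replace = TRUE))
    f <- if (is.null(warm)) NULL else dfe_refit(p, warm)
    reps[b, ] <- c(p$pi_n / p$pi_s, p$dN / p$dS, classic_alpha(p)$alpha,
                   if (is.null(f)) rep(NA_real_, 3)
                   else c(f$alpha, f$omega_a, f$omega_na),
                   p$pi_s)
  }
  qs <- apply(reps, 2, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) c(NA_real_, NA_real_)
    else stats::quantile(v, c(0.025, 0.975), names = FALSE)
  })
  list(est = est, lower = qs[1, ], upper = qs[2, ],
       n_valid = colSums(is.finite(reps)), fit = fit, mk = mk)
}

# Wide report: rows statistic x linkage, columns All/female/male/unbiased,
# cells "estimate [lower-upper]"; #Genes row appended per linkage.
master_table <- function(strata) {
  ci <- strata$ci
  fmt <- function(e, l, u) ifelse(is.na(e), "",
                                  sprintf("%.4g [%.4g; %.4g]", e, l, u))
  stats <- setdiff(stat_names(), "pi_s")
  rows <- list()
  for (s in stats) for (cl in c("autosome", "Z")) {
    cells <- vapply(c("All", "female", "male", "unbiased"), function(ct) {
      r <- ci[ci$stratum == paste(cl, ct, sep = ".") & ci$statistic == s, ]
      if (!nrow(r)) "" else fmt(r$estimate, r$lower, r$upper)
    }, character(1))
    rows[[paste(s, cl)]] <- data.frame(statistic = s, linkage = cl,
                                       t(cells), check.names = FALSE)
  }
  for (cl in c("autosome", "Z")) {
    cells <- vapply(c("All", "female", "male", "unbiased"), function(ct) {
      r <- ci[ci$stratum == paste(cl, ct, sep = ".") &
                ci$statistic == "pi_n_pi_s", ]
      if (!nrow(r)) "0" else as.character(r$n_genes[1])
    }, character(1))
    rows[[paste("n_genes", cl)]] <- data.frame(statistic = "n_genes",
                                               linkage = cl, t(cells),
                                               check.names = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  names(out) <- c("statistic", "linkage", "All", "Female_biased",
                  "Male_biased", "Unbiased")
  out
}

# Synonymous-diversity report: pooled pi_s with CI per linkage and bias
# category, plus the Z:autosome ratio row when available.
pi_s_table <- function(strata, dr = NULL) {
  ci <- strata$ci
  p <- ci[ci$statistic == "pi_s", ]
  out <- data.frame(
    statistic = "pi_s",
    linkage = sub("\\..*$", "", p$stratum),
    category = sub("^[^.]*\\.", "", p$stratum),
    estimate = p$estimate, lower = p$lower, upper = p$upper,
    n_genes = p$n_genes, stringsAsFactors = FALSE
  )
  if (!is.null(dr))
    out <- rbind(out, data.frame(statistic = "pi_sZ_pi_sA", linkage = "NA",
                                 category = "All", estimate = dr$ratio,
                                 lower = dr$lower %||% NA_real_,
                                 upper = dr$upper %||% NA_real_,
                                 n_genes = NA_integer_))
  out
}
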