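# Nei-Gojobori codon statistics: site counting, polymorphism/divergence
# classification, per-site pairwise diversity and SFS extraction from codon
# alignments of n ingroup haplotypes plus one outgroup sequence.

# Synonymous fraction of each of the 3 positions of a codon: number of the 3
# possible single-nucleotide changes at that position that preserve the
# amino acid, over 3. Changes to stop codons count as nonsynonymous.
codon_site_fractions <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  f <- numeric(3)
  for (p in 1:3) {
    for (alt in setdiff(.BASES, ch[p])) {
      nc <- ch; nc[p] <- alt
      if (aa_of(paste(nc, collapse = "")) == aa_of(codon)) f[p] <- f[p] + 1
    }
  }
  f / 3
}

# Synonymous/nonsynonymous classification of a single-base change at
# position pos of a context codon. Returns "s" or "n".
classify_change <- function(ctx, pos, from, to) {
  a <- ctx; a[pos] <- from
  b <- ctx; b[pos] <- to
  a <- paste(a, collapse = ""); b <- paste(b, collapse = "")
  if (aa_of(a) == "*" || aa_of(b) == "*") return("n")
  if (aa_of(a) == aa_of(b)) "s" else "n"
}

# Minimal-pathway averaging between two codons differing at the given
# positions: average synonymous/nonsynonymous step counts over all change
# orders whose intermediates are not stop codons. Falls back to per-site
# classification if every path is blocked.
pathway_average <- function(from_codon, to_codon, positions) {
  perms <- pracma::perms(positions)
  tot_s <- 0; tot_n <- 0; n_paths <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- from_codon
    s <- 0; n <- 0; ok <- TRUE
    for (p in perms[r, ]) {
      nxt <- cur; nxt[p] <- to_codon[p]
      if (aa_of(paste(nxt, collapse = "")) == "*") { ok <- FALSE; break }
      if (aa_of(paste(cur, collapse = "")) == aa_of(paste(nxt, collapse = "")))
        s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_paths <- n_paths + 1 }
  }
  if (n_paths == 0) {
    cls <- vapply(positions, function(p)
      classify_change(from_codon, p, from_codon[p], to_codon[p]), character(1))
    return(c(s = sum(cls == "s"), n = sum(cls == "n")))
  }
  c(s = tot_s / n_paths, n = tot_n / n_paths)
}

#' Count synonymous and nonsynonymous sites in a codon alignment
#'
#' Nei-Gojobori equal-weight site counting on the ingroup consensus codon:
#' each position contributes `f` synonymous sites, where `f` is the number
#' of the 3 possible single-nucleotide changes at that position that are
#' synonymous, divided by 3 (changes to stop codons count as nonsynonymous).
#' Codons containing `N`, a gap, or a stop in any sequence (ingroup or
#' outgroup) are excluded entirely, so `L_n + L_s = 3 * codons_used`.
#'
#' @param aln alignment from [read_codon_alignment()] (or a FASTA path /
#'   `DNAStringSet`, which is read first).
#' @return list with `L_n`, `L_s`, `codons_used`.
#' @examples
#' # a single Phe codon: L_s = 1/3, L_n = 8/3
#' aln <- list(gene_id = "x",
#'             ing = matrix(rep(c("T", "T", "T"), each = 4), nrow = 4),
#'             out = c("T", "T", "T"))
#' count_sites(aln)
#' @export
count_sites <- function(aln) {
  ca <- count_alignment(aln)
  list(L_n = ca$L_n, L_s = ca$L_s, codons_used = ca$codons_used)
}

#' Per-gene polymorphism, divergence and diversity from a codon alignment
#'
#' Walks the alignment codon by codon. A site is polymorphic if two or more
#' ingroup alleles segregate (each non-ancestral allele is one variant,
#' classified by its amino-acid effect on the majority ingroup background of
#' the other two codon positions); a site is a fixed difference if the
#' ingroup is monomorphic and differs from the outgroup; a site that is both
#' polymorphic and divergent counts as polymorphism only. Codons carrying
#' two or more fixed differences are resolved by averaging over minimal
#' mutational pathways, skipping pathways through stop codons. SFS entries
#' use derived-allele counts polarised by the outgroup where its allele is
#' present in the ingroup; otherwise the variant falls in the minor-allele
#' (folded) bin, and the number of such unpolarised sites is recorded.
#' Codons with `N`, a gap or a stop in any sequence are excluded.
#'
#' @param aln alignment from [read_codon_alignment()], a FASTA path, or a
#'   `DNAStringSet` with one `*_outgroup` record.
#' @param jc_correction apply the Jukes-Cantor multiple-hit correction to
#'   `dN` and `dS`? Default `FALSE` (raw per-site proportions).
#' @return one-row `gene_counts` data frame (see [gene_counts_df()]) with
#'   attribute `polarization` = c(polarized, folded) site counts.
#' @export
count_alignment <- function(aln, jc_correction = FALSE) {
  if (!is.list(aln) || is.null(aln$ing)) aln <- read_codon_alignment(aln)
  ing <- aln$ing; outg <- aln$out
  n <- nrow(ing)
  if (n < 4) stop("need at least 4 ingroup sequences (SFS too short)")
  len <- ncol(ing)
  stopifnot(len %% 3 == 0, length(outg) == len)
  n_codons <- len %/% 3

  L_s <- 0; L_n <- 0; codons_used <- 0L
  D_s <- 0; D_n <- 0
  sfs_s <- integer(n - 1); sfs_n <- integer(n - 1)
  het_s <- 0; het_n <- 0
  n_polarized <- 0L; n_folded <- 0L

  for (ci in seq_len(n_codons)) {
    cols <- (3 * ci - 2):(3 * ci)
    sub <- ing[, cols, drop = FALSE]
    oc <- outg[cols]
    if (!all(sub %in% .BASES) || !all(oc %in% .BASES)) next
    ing_codons <- unique(apply(sub, 1, paste, collapse = ""))
    if (any(.GC[ing_codons] == "*") || .GC[paste(oc, collapse = "")] == "*") next

    # majority/consensus codon of the ingroup
    cons <- vapply(1:3, function(p) {
      tab <- allele_counts(sub[, p])
      names(tab)[which.max(tab)]
    }, character(1))
    if (aa_of(paste(cons, collapse = "")) == "*") next

    codons_used <- codons_used + 1L
    f <- codon_site_fractions(paste(cons, collapse = ""))
    L_s <- L_s + sum(f); L_n <- L_n + sum(1 - f)

    fixed_pos <- integer(0)
    for (p in 1:3) {
      tab <- allele_counts(sub[, p])
      if (length(tab) > 1) {
        # polymorphic site
        major <- names(tab)[which.max(tab)]
        anc <- if (oc[p] %in% names(tab)) oc[p] else major
        if (oc[p] %in% names(tab)) n_polarized <- n_polarized + 1L
        else n_folded <- n_folded + 1L
        der <- setdiff(names(tab), anc)
        site_het <- (n^2 - sum(tab^2)) / (n * (n - 1))
        w <- stats::setNames(numeric(length(der)), der)
        cls <- stats::setNames(character(length(der)), der)
        for (a in der) {
          k <- tab[[a]]
          bin <- if (oc[p] %in% names(tab)) k else min(k, n - k)
          cls[a] <- classify_change(cons, p, anc, a)
          w[a] <- k * (n - k)
          if (cls[a] == "s") sfs_s[bin] <- sfs_s[bin] + 1L
          else sfs_n[bin] <- sfs_n[bin] + 1L
        }
        hs <- site_het * w / sum(w)
        het_s <- het_s + sum(hs[cls == "s"])
        het_n <- het_n + sum(hs[cls == "n"])
      } else if (names(tab) != oc[p]) {
        fixed_pos <- c(fixed_pos, p)
      }
    }
    if (length(fixed_pos) == 1) {
      p <- fixed_pos
      cl <- classify_change(cons, p, cons[p], oc[p])
      if (cl == "s") D_s <- D_s + 1 else D_n <- D_n + 1
    } else if (length(fixed_pos) >= 2) {
      to <- cons; to[fixed_pos] <- oc[fixed_pos]
      pa <- pathway_average(cons, to, fixed_pos)
      D_s <- D_s + pa[["s"]]; D_n <- D_n + pa[["n"]]
    }
  }

  if (codons_used == 0L) {
    warning("gene ", aln$gene_id, ": no usable codons")
    gc <- gene_counts_df(aln$gene_id, matrix(0L, 1, n - 1), matrix(0L, 1, n - 1),
                         0, 0, NA_real_, NA_real_, 0L, n, pi_s = NA_real_,
                         pi_n = NA_real_)
    attr(gc, "polarization") <- c(polarized = 0L, folded = 0L)
    return(gc)
  }
  dN <- D_n / L_n; dS <- D_s / L_s
  if (jc_correction) {
    jc <- function(d) -0.75 * log1p(-4 * d / 3)
    dN <- jc(dN); dS <- jc(dS)
  }
  gc <- gene_counts_df(aln$gene_id, matrix(sfs_s, 1), matrix(sfs_n, 1),
                       D_s = D_s, D_n = D_n, L_s = L_s, L_n = L_n,
                       codons_used = codons_used, n_alleles = n,
                       pi_s = het_s / L_s, pi_n = het_n / L_n)
  gc$dN <- dN; gc$dS <- dS
  attr(gc, "polarization") <- c(polarized = n_polarized, folded = n_folded)
  gc
}

allele_counts <- function(col) {
  cnt <- c(A = sum(col == "A"), C = sum(col == "C"),
           G = sum(col == "G"), T = sum(col == "T"))
  cnt[cnt > 0]
}

#' Per-site synonymous and nonsynonymous pairwise diversity
#'
#' `pi_class` is the average over all ingroup sequence pairs of per-site
#' differences of that class divided by the class site total, computed via
#' the unbiased per-site heterozygosity `(n^2 - sum k_a^2) / (n (n-1))`.
#'
#' @inheritParams count_alignment
#' @return named numeric: `pi_n`, `pi_s` (`NA` when the class has no sites).
#' @export
pairwise_diversity <- function(aln) {
  gc <- count_alignment(aln)
  c(pi_n = gc$pi_n, pi_s = gc$pi_s)
}

#' Compute per-gene counts for a set of alignments
#'
#' @param x a directory of FASTA files, a character vector of FASTA paths,
#'   or a named list of `DNAStringSet` alignments (as from
#'   [emit_alignments()]).
#' @param jc_correction passed to [count_alignment()].
#' @return `gene_counts` data frame with one row per gene.
#' @export
gene_counts_from_alignments <- function(x, jc_correction = FALSE) {
  if (is.character(x) && length(x) == 1 && dir.exists(x))
    x <- list.files(x, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (is.character(x)) x <- lapply(x, read_codon_alignment)
  rows <- lapply(x, count_alignment, jc_correction = jc_correction)
  n_all <- vapply(rows, function(r) attr(r, "n_alleles"), integer(1))
  if (length(unique(n_all)) != 1) stop("mixed ingroup sample sizes")
  out <- do.call(rbind, lapply(rows, as.data.frame))
  attr(out, "sfs_s") <- do.call(rbind, lapply(rows, attr, "sfs_s"))
  attr(out, "sfs_n") <- do.call(rbind, lapply(rows, attr, "sfs_n"))
  attr(out, "n_alleles") <- n_all[1]
  attr(out, "folded") <- FALSE
  attr(out, "polarization") <- Reduce(`+`, lapply(rows, attr, "polarization"))
  class(out) <- c("gene_counts", "data.frame")
  out
}
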