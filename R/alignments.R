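# Emission of synthetic codon alignments that realise simulated counts, and
# FASTA reading of ingroup + outgroup codon alignments.

.BASES <- c("A", "C", "G", "T")
.GC <- NULL     # genetic code lookup, filled at load
.NONSTOP <- NULL

.onLoad <- function(libname, pkgname) {
  gc <- Biostrings::GENETIC_CODE
  .GC <<- stats::setNames(as.character(gc), names(gc))
  .NONSTOP <<- names(.GC)[.GC != "*"]
}

aa_of <- function(codon) unname(.GC[codon])

# Eligible single-nucleotide changes of a required class ("s"/"n") in a
# codon; never creates a stop codon. Returns a data frame of (pos, alt).
eligible_changes <- function(codon, class) {
  ch <- strsplit(codon, "")[[1]]
  out <- NULL
  for (p in 1:3) {
    for (alt in setdiff(.BASES, ch[p])) {
      nc <- ch; nc[p] <- alt
      nc <- paste(nc, collapse = "")
      if (aa_of(nc) == "*") next
      cls <- if (aa_of(nc) == aa_of(codon)) "s" else "n"
      if (cls == class) out <- rbind(out, data.frame(pos = p, alt = alt))
    }
  }
  out
}

#' Emit per-gene FASTA codon alignments realising simulated counts
#'
#' For each simulated gene, generates a random stop-free coding sequence and
#' places every simulated polymorphism and fixed difference as a
#' single-nucleotide change of the required class (synonymous or
#' nonsynonymous) on a uniformly chosen eligible codon, at most one variant
#' per codon. Polymorphisms are carried by the required number of ingroup
#' haplotypes (the outgroup keeps the ancestral base); fixed differences are
#' carried by the outgroup only. The resulting alignments round-trip through
#' [count_alignment()] to exactly the simulated totals.
#'
#' @param sim output of [simulate_counts()].
#' @param dir if non-NULL, write one `<gene_id>.fasta` per gene there.
#' @param max_tries attempts to regenerate a gene whose sequence cannot host
#'   its variants without codon collisions before failing.
#' @return named list of `Biostrings::DNAStringSet` alignments (ingroup
#'   haplotypes `<gene>_h1..hn` plus `<gene>_outgroup`), invisibly if `dir`
#'   is given.
#' @export
emit_alignments <- function(sim, dir = NULL, max_tries = 5) {
  stopifnot(inherits(sim, "sim_counts"))
  truth <- attr(sim, "truth")
  n <- attr(sim, "n_alleles")
  sfs_s <- attr(sim, "sfs_s"); sfs_n <- attr(sim, "sfs_n")
  set.seed(truth$seed + 2L)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", nrow(sim))
  names(out) <- sim$gene_id
  for (g in seq_len(nrow(sim))) {
    vars <- rbind(
      variant_spec("s", "poly", sfs_s[g, ]),
      variant_spec("n", "poly", sfs_n[g, ]),
      variant_spec("s", "fixed", k = round(sim$D_s[g])),
      variant_spec("n", "fixed", k = round(sim$D_n[g]))
    )
    n_codons <- max(sim$codons_used[g], ceiling(1.5 * NROW(vars)) + 5)
    aln <- NULL
    for (try in seq_len(max_tries)) {
      aln <- place_variants(vars, n_codons, n)
      if (!is.null(aln)) break
      n_codons <- ceiling(n_codons * 1.5)
    }
    if (is.null(aln))
      stop("gene ", sim$gene_id[g], ": could not host ", NROW(vars),
           " variants after ", max_tries, " attempts")
    seqs <- Biostrings::DNAStringSet(apply(aln, 1, paste, collapse = ""))
    names(seqs) <- c(paste0(sim$gene_id[g], "_h", seq_len(n)),
                     paste0(sim$gene_id[g], "_outgroup"))
    out[[g]] <- seqs
    if (!is.null(dir))
      Biostrings::writeXStringSet(seqs, file.path(dir, paste0(sim$gene_id[g], ".fasta")),
                                  width = 80)
  }
  if (is.null(dir)) out else invisible(out)
}

# Expand an SFS row (or a divergence count) into one row per variant.
variant_spec <- function(class, kind, sfs = NULL, k = NULL) {
  if (kind == "poly") {
    counts <- rep(seq_along(sfs), sfs)
    if (!length(counts)) return(NULL)
    data.frame(class = class, kind = kind, count = counts)
  } else {
    if (!k) return(NULL)
    data.frame(class = class, kind = kind, count = rep(NA_integer_, k))
  }
}

# Lay variants onto a fresh random stop-free sequence; NULL if it cannot be
# done with at most one variant per codon.
place_variants <- function(vars, n_codons, n_alleles) {
  codons <- sample(.NONSTOP, n_codons, replace = TRUE)
  ref <- unlist(strsplit(codons, ""))
  mat <- matrix(rep(ref, n_alleles + 1), nrow = n_alleles + 1, byrow = TRUE)
  if (is.null(vars) || !NROW(vars)) return(mat)
  free <- sample(n_codons)   # random codon visit order, each used once
  ptr <- 1L
  for (v in seq_len(NROW(vars))) {
    placed <- FALSE
    while (ptr <= length(free)) {
      ci <- free[ptr]; ptr <- ptr + 1L
      el <- eligible_changes(codons[ci], vars$class[v])
      if (is.null(el)) next
      pick <- el[sample(NROW(el), 1), ]
      col <- 3 * (ci - 1) + pick$pos
      if (vars$kind[v] == "poly") {
        rows <- sample(n_alleles, vars$count[v])
        mat[rows, col] <- pick$alt
      } else {
        mat[n_alleles + 1, col] <- pick$alt
      }
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  mat
}

#' Read a codon alignment of ingroup haplotypes plus one outgroup
#'
#' @param x a FASTA file path or a `Biostrings::DNAStringSet`. The outgroup
#'   record is identified by an id ending in `_outgroup`.
#' @param gene_id optional id; default is the common record prefix or the
#'   file base name.
#' @return list with `gene_id`, `ing` (character matrix, haplotypes x
#'   positions), `out` (character vector).
#' @export
read_codon_alignment <- function(x, gene_id = NULL) {
  if (is.character(x)) {
    if (is.null(gene_id)) gene_id <- sub("\\.(fa|fasta|fna)$", "", basename(x))
    x <- Biostrings::readDNAStringSet(x)
  }
  stopifnot(inherits(x, "DNAStringSet"))
  ids <- names(x)
  is_out <- grepl("_outgroup$", ids)
  if (sum(is_out) != 1) stop("expected exactly one *_outgroup record")
  if (is.null(gene_id)) gene_id <- sub("_outgroup$", "", ids[is_out])
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1) stop("sequences have unequal lengths")
  if (w[1] %% 3 != 0) stop("alignment length not divisible by 3")
  m <- as.matrix(x)
  list(gene_id = gene_id,
       ing = toupper(m[!is_out, , drop = FALSE]),
       out = toupper(m[is_out, ]))
}
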