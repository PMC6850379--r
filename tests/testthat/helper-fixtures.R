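# Shared fixtures: tiny alignments built in code.

# Build an alignment list (as from read_codon_alignment) from character
# vectors of equal-length sequences; last one is the outgroup.
make_aln <- function(ing, out, gene_id = "g1") {
  list(gene_id = gene_id,
       ing = do.call(rbind, strsplit(toupper(ing), "")),
       out = strsplit(toupper(out), "")[[1]])
}

# A minimal gene_counts object built directly from given per-gene fields.
make_gc <- function(pi_s, pi_n, L_s = 300, L_n = 900, D_s = 20, D_n = 10,
                    n_alleles = 10, chrom_class = NULL) {
  G <- length(pi_s)
  sfs <- matrix(0L, G, n_alleles - 1)
  sfs_s <- sfs; sfs_s[, 1] <- 5L
  sfs_n <- sfs; sfs_n[, 1] <- 3L
  gc <- gene_counts_df(sprintf("g%03d", seq_len(G)), sfs_s, sfs_n,
                       D_s = rep_len(D_s, G), D_n = rep_len(D_n, G),
                       L_s = rep_len(L_s, G), L_n = rep_len(L_n, G),
                       codons_used = rep_len((L_s + L_n) / 3, G),
                       n_alleles = n_alleles,
                       pi_s = pi_s, pi_n = pi_n)
  if (!is.null(chrom_class)) gc$chrom_class <- chrom_class
  gc
}
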