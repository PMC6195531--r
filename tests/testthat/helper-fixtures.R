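# Independent brute-force oracle for the two-sample KS statistic:
# evaluate both ECDFs at every pooled data point and take the sup.
ks_oracle_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Paired dataset fixture built directly from two percentage matrices
# (columns named by codon; remaining codons zero-filled).
paired_from_matrices <- function(me, mn, dataset_label = "fixture",
                                 label_e = "extremophile",
                                 label_ne = "non-extremophile") {
  codons <- codon_alphabet()
  full <- function(m) {
    out <- matrix(0, nrow = nrow(m), ncol = 64,
                  dimnames = list(NULL, codons))
    out[, colnames(m)] <- m
    out
  }
  structure(
    list(dataset_label = dataset_label, n_pairs = nrow(me),
         pair_ids = sprintf("pair_%d", seq_len(nrow(me))),
         matrix_e = full(me), matrix_ne = full(mn),
         label_e = label_e, label_ne = label_ne),
    class = "paired_dataset"
  )
}

# Thermophile-like generator: AGG enriched, CAA depleted by delta of
# within-family mass, all other families uniform.
thermophile_config <- function(n_pairs = 100, gene_length = 300,
                               delta = 0.3, seed = 1L) {
  prof_e <- make_profiles(class_codon_profile(),
                          list(bias_spec("AGG", delta),
                               bias_spec("CAA", -delta)))
  synth_config(n_pairs = n_pairs, gene_length = gene_length,
               profile_e = prof_e, seed = seed)
}

# Single-bias generator: one codon shifted within its family, everything
# else uniform. For a codon from a family with >2 members the target is
# uniquely the most-shifted feature; in a two-codon family (e.g. GAC/GAT)
# the sibling absorbs the full counter-shift and is equally informative.
single_bias_config <- function(codon = "GAC", n_pairs = 100,
                               gene_length = 300, delta = 0.3, seed = 1L) {
  prof_e <- make_profiles(class_codon_profile(),
                          list(bias_spec(codon, delta)))
  synth_config(n_pairs = n_pairs, gene_length = gene_length,
               profile_e = prof_e, seed = seed)
}
gac_config <- function(...) single_bias_config("GAC", ...)
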