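# Shared fixtures and independent oracles used across the test files.

rand_rna <- function(length, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Independent circular-count oracle: circular counting of width w equals
# linear counting of the sequence padded with its first w-1 residues.
# Uses Biostrings when available, else plain substring enumeration.
oracle_circular_counts <- function(seq, width = 3) {
  padded <- paste0(seq, substr(seq, 1, width - 1))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    v <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString(padded),
                                              width = width)
    cnt <- as.integer(v)
    names(cnt) <- chartr("T", "U", names(v))
    cnt
  } else {
    kmers <- substring(padded, seq_len(nchar(seq)),
                       seq_len(nchar(seq)) + width - 1)
    table(factor(kmers, levels = nnnfit::kmer_alphabet(width)))
  }
}

# Exhaustive normal-equations oracle for full-rank least squares.
oracle_normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# Printed inhibition parameters for the packaged independent 12-mer set
# (the published per-12-mer values, one decimal).
printed_independent_P <- c(
  "(ACU)4" = 72.1, "(UUG)4" = 68.2, "(CG)6" = 68.0, "(AACU)3" = 61.7,
  "(GGUC)3" = 61.0, "(UGC)4" = 57.3, "(UUAG)3" = 53.6, "(AACG)3" = 50.3,
  "(AUC)4" = 46.2, "(GGUA)3" = 44.7, "(UCC)4" = 44.2, "(UUGC)3" = 41.2,
  "(AAGC)3" = 39.2, "(AGC)4" = 37.1, "(CCUG)3" = 37.0, "(CCG)4" = 36.8,
  "(A)12" = 35.7, "(GGAC)3" = 34.5, "(ACG)4" = 33.3, "(UUCG)3" = 30.5,
  "(AAG)4" = 29.1, "(UUCA)3" = 28.5, "(CGG)4" = 27.6, "(G)12" = 24.8,
  "(GGCA)3" = 22.7, "(AGG)4" = 22.4, "(GGAU)3" = 19.0, "(AAC)4" = 16.0,
  "(AAUC)3" = 12.2, "(UGG)4" = 11.8, "(U)12" = 9.7, "(ACC)4" = 8.5,
  "(GGCU)3" = 7.3, "(AG)6" = 6.2, "(UUAC)3" = 5.8, "(UCG)4" = 5.6,
  "(AUG)4" = 4.2, "(AUU)4" = 3.2, "(CCAG)3" = 0.4, "(UG)6" = -9.9,
  "(AU)6" = -10.6, "(AAUG)3" = -11.3, "(AGU)4" = -11.8, "(UC)6" = -19.4,
  "(AAU)4" = -22.8, "(AC)6" = -31.8, "(UUC)4" = -36.1, "(C)12" = -44.8,
  "(AAGU)3" = -46.0
)

sim_fixture <- function(seed = 1, n = 112, ...) {
  truth <- generate_truth(seed = seed)
  list(truth = truth,
       experiments = simulate_experiments(truth, n = n, seed = seed + 500, ...))
}
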