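# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by the slowest, most literal
# route so they stay independent of the implementation under test.

BASES <- c("A", "C", "G", "T")

# Literal per-position sum, character by character.
oracle_score <- function(w, kmer) {
  ch <- strsplit(kmer, "")[[1]]
  s <- 0
  for (i in seq_along(ch)) s <- s + unname(w[ch[i], i])
  s
}

# Score every window of a genome string by the literal loop.
oracle_scan <- function(w, seq) {
  k <- ncol(w)
  L <- nchar(seq)
  vapply(seq_len(L - k + 1L), function(start) {
    oracle_score(w, substr(seq, start, start + k - 1L))
  }, numeric(1))
}

# All 4^k DNA strings of width k.
all_kmers <- function(k) {
  grid <- do.call(expand.grid, rep(list(BASES), k))
  apply(as.matrix(grid), 1, paste, collapse = "")
}

# Pairwise-comparison AUROC: fraction of (positive, negative) pairs where
# the positive wins, ties counted half.
oracle_auroc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Random column-stochastic 4 x k frequency matrix.
random_freq_matrix <- function(k, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(4 * k, shape = 1), nrow = 4)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- BASES
    as_frequency_matrix(m)
  })
}

# Random pure-ACGT sequence.
random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(BASES, n, replace = TRUE), collapse = ""))
}

# A point-mass frequency matrix whose consensus is `seq`.
point_mass_freqs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  f <- vapply(ch, function(b) as.numeric(BASES == b), numeric(4))
  rownames(f) <- BASES
  as_frequency_matrix(f)
}

write_temp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("seqs", fileext = ".fasta", tmpdir = dir)
  writeLines(unlist(purrr::imap(records, function(s, nm) c(paste0(">", nm), s))),
             path)
  path
}
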