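# Counts, frequencies, background, log-odds scores, consensus,
# information content, palindromes, degenerate matching.

test_that("count matrix tallies bases per position and keeps column sums", {
  cm <- build_count_matrix(c("ACG", "ACG"))
  expect_equal(unname(cm["A", 1]), 2L)
  expect_equal(unname(cm["C", 2]), 2L)
  expect_equal(unname(cm["G", 3]), 2L)
  expect_equal(sum(cm), 6L)

  cm2 <- build_count_matrix(c("AA", "TT"))
  expect_equal(unname(cm2["A", ]), c(1L, 1L))
  expect_equal(unname(cm2["T", ]), c(1L, 1L))

  # property: columns always sum to the number of sites, on sampled
  # 44-site collections of width 14
  for (seed in 1:5) {
    sites <- sample_sites(cre_like_motif(), n = 44, seed = seed)
    cm <- build_count_matrix(sites)
    expect_equal(unname(colSums(cm)), rep(44, 14))
  }
})

test_that("invalid site collections are rejected with the offending index", {
  expect_error(build_count_matrix(character(0)), class = "crescan_validation_error")
  expect_error(build_count_matrix(c("ACGT", "ACG")), "site 2")
  expect_error(build_count_matrix(c("ACGT", "ACNT")), "site 2")
  expect_error(build_count_matrix(c("A", "C")), "width")
})

test_that("frequencies follow the Laplace pseudocount formula and stay stochastic", {
  cm <- build_count_matrix(c("AC", "AC"))
  f0 <- to_frequencies(cm, pseudocount = 0)
  expect_equal(unname(f0[, 1]), c(1, 0, 0, 0))
  f1 <- to_frequencies(cm, pseudocount = 1)
  expect_equal(unname(f1[, 1]), c(3, 1, 1, 1) / 6)
  expect_error(to_frequencies(cm, pseudocount = -1), class = "crescan_validation_error")

  # property: every column re-sums to 1 for arbitrary counts and pseudocounts
  for (seed in 1:10) {
    sites <- sample_sites(random_freq_matrix(8, seed), n = 7, seed = seed + 100)
    f <- to_frequencies(build_count_matrix(sites), pseudocount = 0.5)
    resum <- vapply(seq_len(ncol(f)), function(i) sum(f[, i]), numeric(1))
    expect_true(all(abs(resum - 1) < 1e-9))
  }
})

test_that("background estimation counts composition and floors zeros", {
  bg <- estimate_background("AACCGGTT")
  expect_equal(unname(as.numeric(bg)), rep(0.25, 4))

  expect_warning(bg0 <- estimate_background("AAAA"), "floored")
  expect_true(all(as.numeric(bg0) > 0))
  expect_equal(sum(as.numeric(bg0)), 1)

  # strand averaging symmetrizes A/T and C/G
  bgs <- estimate_background("AAAC", both_strands = TRUE)
  expect_equal(bgs[["A"]], bgs[["T"]])
  expect_equal(bgs[["C"]], bgs[["G"]])

  # sampled 10 kb genome recovers its generating composition within 0.02
  p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  g <- synth_genome(10000, background = background_model(p), seed = 7)
  expect_true(all(abs(as.numeric(estimate_background(g)) - p) < 0.02))
})

test_that("log-odds scores are zero at background and additive in bits", {
  # a column matching the background scores zero everywhere
  f <- as_frequency_matrix(matrix(0.25, 4, 5, dimnames = list(BASES, NULL)))
  pssm <- build_pssm(f, uniform_background())
  expect_equal(unname(pssm$w), matrix(0, 4, 5), ignore_attr = TRUE)
  expect_equal(score_kmer(pssm, "ACGTA"), 0)

  # single perfectly conserved site, no pseudocount: 2 bits per position
  one <- build_pssm(to_frequencies(build_count_matrix("ACGT"), 0), uniform_background())
  expect_equal(score_kmer(one, "ACGT"), 8)

  # zero frequencies: -Inf under the default policy, error under strict
  f0 <- to_frequencies(build_count_matrix(c("AA", "AA")), 0)
  expect_error(build_pssm(f0, on_zero = "error"), class = "crescan_validation_error")
  expect_true(any(is.infinite(build_pssm(f0)$w)))

  # additivity: score equals the literal per-position sum
  for (seed in 1:10) {
    pssm <- build_pssm(random_freq_matrix(6, seed), uniform_background())
    kmer <- random_dna(6, seed + 50)
    expect_equal(score_kmer(pssm, kmer), oracle_score(pssm$w, kmer))
  }

  expect_error(score_kmer(one, "ACG"), class = "crescan_validation_error")
  expect_error(score_kmer(one, "ACNT"), class = "crescan_validation_error")
})

test_that("consensus maximizes the additive score with A<C<G<T tie-break", {
  # exhaustive check at k = 4
  for (seed in 1:5) {
    pssm <- build_pssm(random_freq_matrix(4, seed), uniform_background())
    cons <- consensus_sequence(pssm)
    scores <- vapply(all_kmers(4), function(s) oracle_score(pssm$w, s), numeric(1))
    expect_equal(cons$score, max(scores))
  }
  # tie between C and G resolves to C
  f <- as_frequency_matrix(matrix(c(0.1, 0.4, 0.4, 0.1), 4, 1,
                                  dimnames = list(BASES, NULL)))
  expect_equal(consensus_sequence(build_pssm(f))$sequence, "C")
})

test_that("information content is the per-column relative entropy", {
  f <- as_frequency_matrix(cbind(rep(0.25, 4), c(1, 0, 0, 0)))
  ic <- information_content(f, uniform_background())
  expect_equal(ic, c(0, 2))

  # random column against a literal KL oracle
  for (seed in 1:10) {
    fr <- random_freq_matrix(3, seed)
    bg <- background_model(c(0.3, 0.2, 0.2, 0.3))
    ic <- information_content(fr, bg)
    p <- as.numeric(bg)
    kl <- vapply(1:3, function(i) {
      s <- 0
      for (b in 1:4) if (fr[b, i] > 0) s <- s + fr[b, i] * log2(fr[b, i] / p[b])
      s
    }, numeric(1))
    expect_equal(ic, kl)
  }
})

test_that("palindrome positions count complement-mirrored half-site pairs", {
  expect_equal(palindrome_positions("AT")$count, 1)
  expect_equal(palindrome_positions("AA")$count, 0)
  expect_error(palindrome_positions("ACG"), class = "crescan_validation_error")
  expect_error(palindrome_positions("ACNT"), class = "crescan_validation_error")

  # invariance under reverse complement, on random even-width sequences
  for (seed in 1:20) {
    s <- random_dna(2 * sample(2:9, 1), seed)
    expect_equal(palindrome_positions(revcomp(s))$count,
                 palindrome_positions(s)$count)
  }

  tb <- palindrome_table(c("AT", "TGAAAGCGCTTTCA"))
  expect_equal(tb$count, c(1, 7))
  expect_equal(tb$mask[1], "*")
})

test_that("degenerate IUPAC matching counts per-position set membership", {
  # manual oracle with its own expansion table
  expand <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
                 W = c("A", "T"), S = c("C", "G"), B = c("C", "G", "T"))
  seq <- "TGAACGCGCGTACA"
  pat <- "TGNAANCGNWNNCW"
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pat, "")[[1]]
  expected <- sum(!mapply(function(b, p) b %in% expand[[p]], sc, pc))

  res <- degenerate_match(seq, pat)
  expect_equal(res$mismatches, expected)
  expect_false(res$match)

  expect_true(degenerate_match("ACGTACGTACGTAC", strrep("N", 14))$match)
  expect_false(degenerate_match("A", "B")$match)
  expect_error(degenerate_match("A", "Z"), class = "crescan_validation_error")
  expect_error(degenerate_match("AC", "NNN"), class = "crescan_validation_error")
})
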