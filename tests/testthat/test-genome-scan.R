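# FASTA reading, window scoring, streaming summary, hit calling,
# coordinate conventions and BED round-trips.

test_that("FASTA genomes read in order, uppercased, short contigs excluded", {
  path <- write_temp_fasta(list(chr1 = "acgtacgtacgt", chr2 = "GGGGCCCC"))
  g <- read_genome(path)
  expect_equal(g$id, c("chr1", "chr2"))
  expect_equal(g$sequence[1], "ACGTACGTACGT")
  expect_equal(g$length, c(12L, 8L))

  pssm <- build_pssm(random_freq_matrix(10, 1), uniform_background())
  expect_warning(scan <- scan_genome(g, pssm), "shorter than the motif width")
  expect_true(all(scan$contig == "chr1"))

  expect_error(read_genome(tempfile()), class = "crescan_validation_error")
})

test_that("forward scan emits one window per start and skips ambiguous windows", {
  zero <- pssm_from_matrix(matrix(0, 4, 2, dimnames = list(BASES, NULL)))
  scan <- scan_genome("AAAA", zero)
  expect_equal(nrow(scan), 3L)
  expect_equal(scan$score, c(0, 0, 0))
  expect_equal(scan$end - scan$start + 1L, rep(2L, 3))

  # window-count conservation with an ambiguous base: scored + skipped = L - k + 1
  scanN <- scan_genome("AANTAA", zero)
  smry <- scan_summary(scanN)
  expect_equal(smry$n_scored + smry$n_skipped, 6L - 2L + 1L)
  expect_equal(smry$n_skipped, 2L)
  expect_false(any(scanN$start %in% c(2L, 3L)))
})

test_that("scan scores agree window-by-window with a brute-force scorer", {
  g <- synth_genome(5000, background = default_background(), seed = 11)
  pssm <- build_pssm(random_freq_matrix(14, 3), default_background())
  scan <- scan_genome(g, pssm, chunk_size = 700L)  # force several chunks
  expected <- oracle_scan(pssm$w, g$sequence)
  expect_equal(nrow(scan), length(expected))
  expect_true(max(abs(scan$score - expected)) < 1e-9)

  smry <- scan_summary(scan)
  expect_equal(smry$mean, mean(expected), tolerance = 1e-12)
  expect_equal(smry$sd, sd(expected), tolerance = 1e-9)
  expect_equal(c(smry$min, smry$max), c(min(expected), max(expected)))
})

test_that("minus-strand scores equal forward scores of the reverse complement", {
  g <- synth_genome(300, seed = 5)
  pssm <- build_pssm(random_freq_matrix(8, 9), uniform_background())
  both <- scan_genome(g, pssm, strand_mode = "both", emit = "both")
  fwd <- both[both$strand == "+", ]
  rev <- both[both$strand == "-", ]
  expect_equal(nrow(fwd), nrow(rev))
  seqs <- substring(g$sequence, rev$start, rev$end)
  expect_equal(rev$score, score_kmer(pssm, revcomp(seqs)))

  # best-strand mode keeps the per-position maximum
  best <- scan_genome(g, pssm, strand_mode = "both", emit = "best")
  expect_equal(best$score, pmax(fwd$score, rev$score))
})

test_that("hit calling thresholds, sorts by score and recovers planted sites", {
  g <- synth_genome(2000, seed = 21)
  pssm <- build_pssm(random_freq_matrix(6, 2), uniform_background())
  scan <- scan_genome(g, pssm)
  expect_equal(nrow(call_hits(scan, max(scan$score) + 1)), 0L)
  all_in <- call_hits(scan, min(scan$score))
  expect_equal(nrow(all_in), nrow(scan))
  expect_true(all(diff(all_in$score) <= 0))

  # five planted consensus sites sit alone above a midway threshold
  freqs <- cre_like_motif()
  cons <- consensus_sequence(build_pssm(freqs, uniform_background()))$sequence
  genome <- synth_genome(20000, seed = 31)
  positions <- c(1000L, 5000L, 9000L, 13000L, 17000L)
  bench <- plant_sites(genome, point_mass_freqs(cons), m = 5,
                       positions = positions, seed = 32)
  trained <- build_pssm(to_frequencies(build_count_matrix(
    sample_sites(freqs, 44, seed = 33)), 0.5), uniform_background())
  scan <- scan_genome(bench$genome, trained)
  cons_score <- score_kmer(trained, cons)
  bg_max <- max(scan$score[!scan$start %in% positions])
  expect_true(cons_score > bg_max)  # construction guarantees separation
  hits <- call_hits(scan, (cons_score + bg_max) / 2)
  expect_setequal(hits$start, positions)
})

test_that("BED export converts coordinates, round-trips, and is byte-stable", {
  hits <- tibble::tibble(contig = "NC_000001", start = 3308248L, end = 3308261L,
                         strand = "+", score = 9.18)
  path <- tempfile(fileext = ".bed")
  write_bed(hits, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#contig\tstart\tend\tname\tscore\tstrand")
  expect_equal(lines[2], "NC_000001\t3308247\t3308261\thit_1\t9.18\t+")

  back <- read_bed(path)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$score, hits$score)

  # empty table still writes the self-describing header
  empty_path <- tempfile(fileext = ".bed")
  write_bed(hits[0, ], empty_path)
  expect_equal(readLines(empty_path), "#contig\tstart\tend\tname\tscore\tstrand")

  # identical scans produce byte-identical BED output
  g <- synth_genome(3000, seed = 41)
  pssm <- build_pssm(random_freq_matrix(10, 4), uniform_background())
  p1 <- tempfile(); p2 <- tempfile()
  write_bed(call_hits(scan_genome(g, pssm), 2), p1)
  write_bed(call_hits(scan_genome(g, pssm), 2), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
})

test_that("hits annotate as within-CDS, upstream, or intergenic", {
  genes <- tibble::tibble(
    contig = "chr", start = c(1000L, 5000L), end = c(2000L, 6000L),
    strand = c("+", "-"), name = c("geneA", "geneB"))
  hits <- tibble::tibble(
    contig = "chr",
    start = c(1500L, 886L, 6101L, 3000L),
    end = c(1513L, 899L, 6114L, 3013L),
    strand = "+", score = 10)
  ann <- annotate_nearest_feature(hits, genes)
  expect_equal(ann$location, c("within CDS", "upstream", "upstream", "intergenic"))
  expect_equal(ann$gene, c("geneA", "geneA", "geneB", NA))
  # + gene: gap from hit end to gene start; - gene: from gene end to hit start
  expect_equal(ann$distance, c(0, 1000 - 899, 6101 - 6000, NA))

  expect_error(annotate_nearest_feature(hits, dplyr::mutate(genes, contig = "other")),
               class = "crescan_validation_error")
})

test_that("a site inside a coding region annotates as within-CDS at table-like coordinates", {
  # gene table mimicking a cellulase gene-cluster layout: the scanned hit
  # inside the mannanase ORF must label as within CDS
  genes <- tibble::tibble(
    contig = "NC_017304",
    start = c(3307000L, 3316800L, 3318900L),
    end = c(3308400L, 3318400L, 3320500L),
    strand = "+",
    name = c("celC", "manB", "celT"))
  hit <- tibble::tibble(contig = "NC_017304", start = 3317291L, end = 3317304L,
                        strand = "+", score = 14.62)
  ann <- annotate_nearest_feature(hit, genes)
  expect_equal(ann$gene, "manB")
  expect_equal(ann$location, "within CDS")
})
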