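# High-level pipeline stages backing the command-line interface.  Each
# stage writes its outputs plus the resolved configuration into `out_dir`
# and returns its central object invisibly.

log_stage <- function(stage, ...) {
  message(sprintf("[crescan] %s | %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " ")))
}

resolve_background <- function(mode, genome = NULL) {
  switch(mode,
    uniform = uniform_background(),
    genome = {
      if (is.null(genome)) stop_invalid("background = \"genome\" needs a genome to estimate from.")
      estimate_background(genome)
    },
    stop_invalid(sprintf("Unknown background mode: %s", mode)))
}

#' Build a PSSM from a site file
#'
#' Reads the aligned sites, tallies counts, normalizes with the
#' pseudocount, and writes the frequency matrix, the log-odds matrix
#' (bits), the consensus, the per-position information content, the
#' training sites' own scores, and the resolved configuration.
#'
#' @param sites_path Site collection (FASTA or one-per-line text).
#' @param out_dir Output directory.
#' @param pseudocount Per-cell pseudocount; default 0.5.
#' @param background_genome Optional FASTA whose composition becomes the
#'   background; without it the background is uniform.
#' @return The fitted `pssm`, invisibly.
#' @export
run_build <- function(sites_path, out_dir, pseudocount = 0.5,
                      background_genome = NULL) {
  sites <- read_sites(sites_path)
  counts <- build_count_matrix(sites)
  freqs <- to_frequencies(counts, pseudocount = pseudocount)
  bg <- if (is.null(background_genome)) uniform_background()
        else estimate_background(read_genome(background_genome))
  pssm <- build_pssm(freqs, background = bg)
  ic <- information_content(freqs, bg)
  cons <- consensus_sequence(pssm)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(freqs, file.path(out_dir, "frequencies.tsv"))
  write_matrix_tsv(pssm, file.path(out_dir, "pssm.tsv"))
  readr::write_tsv(tibble(position = seq_along(ic), ic_bits = ic),
                   file.path(out_dir, "information_content.tsv"))
  readr::write_tsv(tibble(name = sites$name, site = sites$site,
                          score = score_kmer(pssm, sites$site)),
                   file.path(out_dir, "training_scores.tsv"))
  readr::write_tsv(tibble(consensus = cons$sequence,
                          consensus_score = cons$score,
                          total_ic = sum(ic),
                          n_sites = nrow(sites), width = pssm$k),
                   file.path(out_dir, "build_report.tsv"))
  write_run_config(run_config(pseudocount = pseudocount,
                              background = if (is.null(background_genome)) "uniform" else "genome",
                              background_probs = round(as.numeric(bg), 6)),
                   out_dir)
  log_stage("build", n_sites = nrow(sites), width = pssm$k,
            total_ic = sprintf("%.2f", sum(ic)))
  invisible(pssm)
}

#' Scan a genome with a stored matrix
#'
#' @param matrix_path Log-odds matrix TSV (see [read_matrix_tsv()]).
#' @param genome_path Genome FASTA.
#' @param out_dir Output directory (hits BED + scan summary + config).
#' @param threshold Hit-calling threshold in bits; default 12.
#' @param strand `"forward"` or `"both"`.
#' @param genes Optional gene table (BED/GFF3) for proximity annotation.
#' @param upstream_window Promoter window in bp for `"upstream"` calls.
#' @return The annotated `hit_table`, invisibly.
#' @export
run_scan <- function(matrix_path, genome_path, out_dir, threshold = 12,
                     strand = "forward", genes = NULL, upstream_window = 500) {
  pssm <- pssm_from_matrix(read_matrix_tsv(matrix_path))
  genome <- read_genome(genome_path)
  scan <- scan_genome(genome, pssm, strand_mode = strand)
  hits <- call_hits(scan, threshold)
  if (!is.null(genes)) {
    hits <- annotate_nearest_feature(hits, read_features(genes),
                                     upstream_window = upstream_window)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(hits, file.path(out_dir, "hits.bed"))
  smry <- scan_summary(scan)
  smry$n_hits <- nrow(hits)
  smry$threshold <- threshold
  readr::write_tsv(smry, file.path(out_dir, "scan_summary.tsv"))
  if (!is.null(genes)) {
    readr::write_tsv(as_tibble(hits), file.path(out_dir, "hits_annotated.tsv"))
  }
  write_run_config(run_config(strand = strand, threshold = threshold,
                              upstream_window = upstream_window),
                   out_dir)
  log_stage("scan", windows = smry$n_scored, skipped = smry$n_skipped,
            mean = sprintf("%.2f", smry$mean), hits = nrow(hits))
  invisible(hits)
}

#' Calibrate a detection threshold by ROC on a genome with known sites
#'
#' @param matrix_path Log-odds matrix TSV.
#' @param genome_path Calibration genome FASTA.
#' @param known_path Known sites: a BED file (coordinate mode) or a
#'   FASTA/text site file (sequence mode), distinguished by content.
#' @param out_dir Output directory (ROC TSV + chosen threshold + config).
#' @param thresholds Grid string `"lo:hi:step"`; default `"9:19:1"`.
#' @param strand `"forward"` or `"both"`.
#' @return The `roc_curve`, invisibly.
#' @export
run_roc <- function(matrix_path, genome_path, known_path, out_dir,
                    thresholds = "9:19:1", strand = "forward") {
  pssm <- pssm_from_matrix(read_matrix_tsv(matrix_path))
  genome <- read_genome(genome_path)
  scan <- scan_genome(genome, pssm, strand_mode = strand)
  if (grepl("\\.bed$", known_path, ignore.case = TRUE)) {
    labeled <- label_windows(scan, read_bed(known_path), mode = "coordinates")
  } else {
    labeled <- label_windows(scan, read_sites(known_path)$site,
                             mode = "sequences", genome = genome)
  }
  grid <- threshold_grid(thresholds)
  curve <- roc_curve(labeled, grid)
  chosen <- choose_threshold(curve, "youden")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(as_tibble(curve), file.path(out_dir, "roc.tsv"))
  readr::write_tsv(dplyr::bind_cols(chosen, tibble(auroc = attr(curve, "auroc"))),
                   file.path(out_dir, "chosen_threshold.tsv"))
  write_run_config(run_config(thresholds = thresholds, strand = strand), out_dir)
  log_stage("roc", n_pos = attr(curve, "n_pos"), n_neg = attr(curve, "n_neg"),
            auroc = sprintf("%.4f", attr(curve, "auroc")),
            youden = chosen$threshold)
  invisible(curve)
}

#' Generate a benchmark directory
#'
#' Writes training sites (FASTA), the planted genome (FASTA), the truth
#' table (BED) and the resolved configuration of a
#' [simulate_benchmark()] run.
#'
#' @param out_dir Output directory.
#' @param n_sites,genome_length,n_planted,seed Benchmark parameters; see
#'   [simulate_benchmark()].
#' @param strand_policy Planting strand policy.
#' @return The `synthetic_benchmark`, invisibly.
#' @export
run_simulate <- function(out_dir, n_sites = 44, genome_length = 100000,
                         n_planted = 10, strand_policy = "forward", seed = 1L) {
  bench <- simulate_benchmark(n_sites = n_sites, genome_length = genome_length,
                              n_planted = n_planted, strand_policy = strand_policy,
                              seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sites_fasta(bench$sites, file.path(out_dir, "sites.fasta"))
  write_genome(bench$genome, file.path(out_dir, "genome.fasta"))
  write_bed(bench$truth, file.path(out_dir, "truth.bed"),
            names = sprintf("planted_%d", seq_len(nrow(bench$truth))))
  write_run_config(run_config(n_sites = n_sites, genome_length = genome_length,
                              n_planted = n_planted, strand = strand_policy,
                              seed = seed),
                   out_dir)
  log_stage("simulate", n_sites = n_sites, L = genome_length, planted = n_planted,
            seed = seed)
  invisible(bench)
}
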