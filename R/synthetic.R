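# Seeded synthetic-data generators: site collections drawn column-wise
# from a frequency matrix, i.i.d. background genomes, and genomes with
# motif instances planted at recorded positions.

#' A cre-like 14-column motif frequency matrix
#'
#' Frequencies shaped on the degenerate catabolite-responsive-element
#' consensus `TGNAANCGNWNNCW`: fully specified positions put
#' `conservation` on the consensus base (the remainder spread evenly),
#' `W` positions split `2 * w_weight` between A and T, and `N` positions
#' are uniform.  With the defaults the motif carries about 12.4 bits of
#' total information against a uniform background — strongly conserved,
#' as bacterial operator alignments typically are, and enough for planted
#' sites to stand clear of background in genomes up to about 1 Mb.
#'
#' @param conservation Weight on the consensus base at fully specified
#'   positions; default 0.94.
#' @param w_weight Weight on each of A and T at `W` positions; default
#'   0.47.
#' @return A 4 x 14 `frequency_matrix`.
#' @export
cre_like_motif <- function(conservation = 0.94, w_weight = 0.47) {
  pat <- strsplit("TGNAANCGNWNNCW", "")[[1]]
  f <- vapply(pat, function(p) {
    switch(p,
      N = rep(0.25, 4),
      W = { v <- rep((1 - 2 * w_weight) / 2, 4); v[c(1, 4)] <- w_weight; v },
      { v <- rep((1 - conservation) / 3, 4); v[match(p, DNA_BASES)] <- conservation; v })
  }, numeric(4))
  dimnames(f) <- list(DNA_BASES, NULL)
  structure(f, pseudocount = 0, n_sites = NA_integer_,
            class = c("frequency_matrix", "matrix", "array"))
}

#' Default background composition for synthetic genomes
#'
#' GC content 0.435, typical of the Firmicutes genomes used to calibrate
#' cre-like matrices.
#'
#' @return A `background_model`.
#' @export
default_background <- function() {
  background_model(c(A = 0.2825, C = 0.2175, G = 0.2175, T = 0.2825))
}

check_freq_matrix <- function(freqs) {
  f <- unclass(freqs)
  if (!is.matrix(f) || nrow(f) != 4L) stop_invalid("Frequency matrix must be 4 x k.")
  if (any(f < 0) || any(abs(colSums(f) - 1) > 1e-6)) {
    stop_invalid("Frequency matrix columns must be probability distributions.")
  }
  f
}

#' Sample aligned binding sites from a frequency matrix
#'
#' Each position of each site is drawn independently from the matrix
#' column (product-multinomial model, matching the additivity assumption
#' of the scoring matrix).
#'
#' @param freqs 4 x k `frequency_matrix`.
#' @param n Number of sites; the study-scale default is 44, the size of
#'   a typical curated cre-site collection.
#' @param seed Integer seed; the same seed reproduces the collection
#'   exactly.
#' @return Tibble with `name` and `site` columns.
#' @export
sample_sites <- function(freqs, n = 44, seed = 1L) {
  f <- check_freq_matrix(freqs)
  if (n < 1) stop_invalid("`n` must be at least 1.")
  k <- ncol(f)
  withr::with_seed(seed, {
    draws <- vapply(seq_len(k),
                    function(i) sample(DNA_BASES, n, replace = TRUE, prob = f[, i]),
                    character(n))
    if (n == 1L) draws <- matrix(draws, nrow = 1L)
    tibble(name = sprintf("site_%03d", seq_len(n)),
           site = apply(draws, 1, paste, collapse = ""))
  })
}

#' Generate an i.i.d. background genome
#'
#' @param length Genome length in bp.
#' @param background A `background_model`; default [default_background()].
#' @param seed Integer seed.
#' @param id Contig identifier.
#' @return Genome tibble (`id`, `sequence`, `length`) compatible with
#'   [scan_genome()].
#' @export
synth_genome <- function(length, background = default_background(), seed = 1L,
                         id = "synthetic_contig_1") {
  if (length < 1) stop_invalid("Genome length must be at least 1.")
  p <- as.numeric(background)
  withr::with_seed(seed, {
    seq <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  tibble(id = id, sequence = seq, length = nchar(seq))
}

#' Plant motif instances into a genome at recorded positions
#'
#' Draws `m` site sequences from the frequency matrix and substitutes
#' them (in place — genome length and downstream coordinates are
#' preserved) at non-overlapping positions, either supplied or sampled
#' uniformly with rejection.  Sites planted on the minus strand are
#' reverse-complemented before substitution, so scanning the plus strand
#' of the genome recovers them only in `"both"` strand mode.
#'
#' @param genome Genome tibble (single contig or more; positions refer to
#'   the first contig unless `contig` is given).
#' @param freqs 4 x k `frequency_matrix` the planted sites are drawn
#'   from.
#' @param m Number of sites to plant.
#' @param positions Optional integer vector of 1-based start positions;
#'   `NULL` samples non-overlapping positions at random.
#' @param strand_policy `"forward"` plants all sites on `+`; `"both"`
#'   picks a strand uniformly per site.
#' @param seed Integer seed.
#' @param contig Contig id to plant into; default the first.
#' @param max_tries Rejection-sampling budget for random placement.
#' @return A list of class `synthetic_benchmark`: `genome` (with sites
#'   substituted) and `truth` (tibble `contig`, `start`, `end`, `strand`,
#'   `site`, sorted by `start`).
#' @export
plant_sites <- function(genome, freqs, m, positions = NULL,
                        strand_policy = c("forward", "both"), seed = 1L,
                        contig = NULL, max_tries = 1000L) {
  strand_policy <- match.arg(strand_policy)
  f <- check_freq_matrix(freqs)
  k <- ncol(f)
  if (is.null(contig)) contig <- genome$id[1]
  ci <- match(contig, genome$id)
  if (is.na(ci)) stop_invalid(sprintf("Contig %s not found in the genome.", contig))
  L <- genome$length[ci]
  if (m * k > L) stop_invalid("Planted sites do not fit: m * k exceeds the genome length.")

  truth <- tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), site = character())
  if (m > 0) {
    withr::with_seed(seed, {
      if (is.null(positions)) {
        positions <- integer(0)
        tries <- 0L
        while (length(positions) < m) {
          cand <- sample.int(L - k + 1L, 1L)
          if (all(abs(cand - positions) >= k)) {
            positions <- c(positions, cand)
          } else {
            tries <- tries + 1L
            if (tries > max_tries) stop_invalid("Could not place non-overlapping sites; genome too crowded.")
          }
        }
      } else {
        positions <- as.integer(positions)
        if (length(positions) != m) stop_invalid("`positions` must have length `m`.")
        if (any(positions < 1L | positions > L - k + 1L)) stop_invalid("Planting position out of range.")
        if (m > 1 && min(diff(sort(positions))) < k) stop_invalid("Supplied planting positions overlap.")
      }
      sites <- sample_sites(f, n = m, seed = sample.int(2^31 - 1L, 1L))$site
      strands <- if (strand_policy == "both") sample(c("+", "-"), m, replace = TRUE)
                 else rep("+", m)
      seq <- genome$sequence[ci]
      for (j in seq_len(m)) {
        ins <- if (strands[j] == "-") revcomp(sites[j]) else sites[j]
        substr(seq, positions[j], positions[j] + k - 1L) <- ins
      }
      genome$sequence[ci] <- seq
      truth <- tibble(contig = contig, start = positions,
                      end = positions + k - 1L, strand = strands, site = sites) |>
        dplyr::arrange(.data$start)
    })
  }
  structure(list(genome = genome, truth = truth), class = "synthetic_benchmark")
}

#' One-call ground-truthed benchmark
#'
#' Generates the full desk-scale study setup: a training collection of
#' `n_sites` aligned sites drawn from `freqs`, a background genome of
#' `genome_length` bp, and `n_planted` additional draws planted at known
#' non-overlapping positions.  Defaults mirror the cross-species cre-site
#' setting: 44 training sites of width 14, a 100 kb genome at GC 0.435,
#' 10 planted sites.
#'
#' @param freqs Generating `frequency_matrix`; default [cre_like_motif()].
#' @param n_sites Training-collection size.
#' @param genome_length Background genome length in bp.
#' @param background A `background_model`.
#' @param n_planted Number of planted sites.
#' @param strand_policy Passed to [plant_sites()].
#' @param seed Integer seed; sub-generators are seeded deterministically
#'   from it.
#' @return A list of class `synthetic_benchmark`: `sites`, `genome`,
#'   `truth`, `freqs`, and the resolved `spec` (parameters + seed).
#' @export
simulate_benchmark <- function(freqs = cre_like_motif(), n_sites = 44,
                               genome_length = 100000, background = default_background(),
                               n_planted = 10, strand_policy = "forward", seed = 1L) {
  seed <- as.integer(seed)
  sites <- sample_sites(freqs, n = n_sites, seed = seed)
  genome <- synth_genome(genome_length, background = background, seed = seed + 1L)
  planted <- plant_sites(genome, freqs, m = n_planted,
                         strand_policy = strand_policy, seed = seed + 2L)
  structure(list(sites = sites, genome = planted$genome, truth = planted$truth,
                 freqs = freqs,
                 spec = list(n_sites = n_sites, genome_length = genome_length,
                             background = as.numeric(background),
                             n_planted = n_planted, strand_policy = strand_policy,
                             seed = seed)),
            class = "synthetic_benchmark")
}

#' Recovery metrics of a pipeline run against planted truth
#'
#' @param truth Truth tibble from [plant_sites()] /
#'   [simulate_benchmark()].
#' @param hits A `hit_table` on the same genome.
#' @param labeled Optional `labeled_windows` to report AUROC.
#' @param freqs_true,freqs_est Optional generating and re-estimated
#'   frequency matrices to report the maximum absolute cell error.
#' @return One-row tibble: `n_planted`, `n_hits`, `sensitivity`
#'   (fraction of planted starts present in the hit table), and, when
#'   available, `auroc` and `max_freq_error`.
#' @export
recovery_report <- function(truth, hits, labeled = NULL,
                            freqs_true = NULL, freqs_est = NULL) {
  hit_key <- paste(hits$contig, hits$start)
  sens <- if (nrow(truth) == 0L) NA_real_
          else mean(paste(truth$contig, truth$start) %in% hit_key)
  out <- tibble(n_planted = nrow(truth), n_hits = nrow(hits), sensitivity = sens)
  if (!is.null(labeled)) out$auroc <- auroc(labeled)
  if (!is.null(freqs_true) && !is.null(freqs_est)) {
    out$max_freq_error <- max(abs(unclass(freqs_true) - unclass(freqs_est)))
  }
  out
}
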