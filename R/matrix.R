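# Motif model: counts -> frequencies -> log-odds bits, plus consensus,
# information content, palindrome symmetry and degenerate matching.

#' Tally base counts per motif position
#'
#' @param sites A tibble with a `site` column (e.g. from [read_sites()]) or
#'   a character vector of equal-width A/C/G/T sequences.
#' @return A 4 x k integer matrix (rows A, C, G, T) of class
#'   `count_matrix`, with the number of sites attached as attribute
#'   `n_sites`.  Every column sums to the number of sites.
#' @examples
#' build_count_matrix(c("ACG", "ACG", "ATG"))
#' @export
build_count_matrix <- function(sites) {
  s <- as_site_vector(sites)
  k <- nchar(s[1])
  chars <- matrix(unlist(strsplit(s, "", fixed = TRUE)),
                  nrow = length(s), ncol = k, byrow = TRUE)
  counts <- vapply(seq_len(k),
                   function(i) tabulate(match(chars[, i], DNA_BASES), 4L),
                   integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(counts, n_sites = length(s), class = c("count_matrix", "matrix", "array"))
}

n_sites_of <- function(counts) {
  n <- attr(counts, "n_sites")
  if (is.null(n)) n <- unique(colSums(counts))[1]
  n
}

#' Normalize counts to column-stochastic frequencies
#'
#' Applies a Laplace-style pseudocount: `f[b,i] = (counts[b,i] + a) /
#' (n_sites + 4 a)`, so every column sums to 1 and, for `a > 0`, every
#' entry is strictly positive (finite log-odds downstream).
#'
#' @param counts A `count_matrix` from [build_count_matrix()] or any 4 x k
#'   non-negative matrix with rows A, C, G, T.
#' @param pseudocount Non-negative constant added to each cell; default
#'   0.5.
#' @return A 4 x k `frequency_matrix` with attributes `pseudocount` and
#'   `n_sites`.
#' @export
to_frequencies <- function(counts, pseudocount = 0.5) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop_invalid("`pseudocount` must be a single non-negative number.")
  }
  m <- unclass(counts)
  n <- n_sites_of(counts)
  f <- sweep(m + pseudocount, 2, colSums(m) + 4 * pseudocount, "/")
  structure(f, pseudocount = pseudocount, n_sites = n,
            class = c("frequency_matrix", "matrix", "array"))
}

#' Uniform background distribution
#'
#' @return A named probability vector (A, C, G, T), all 0.25, of class
#'   `background_model`.
#' @export
uniform_background <- function() {
  structure(stats::setNames(rep(0.25, 4), DNA_BASES), class = "background_model")
}

#' Explicit background distribution
#'
#' @param p Numeric vector of 4 probabilities in A, C, G, T order (or
#'   named); must be positive and sum to 1 (renormalized if slightly off).
#' @return A `background_model`.
#' @export
background_model <- function(p) {
  if (length(p) != 4L) stop_invalid("A background model needs 4 probabilities (A, C, G, T).")
  if (!is.null(names(p))) p <- p[DNA_BASES]
  if (any(is.na(p)) || any(p <= 0)) {
    stop_invalid("Background probabilities must all be positive.")
  }
  p <- p / sum(p)
  structure(stats::setNames(as.numeric(p), DNA_BASES), class = "background_model")
}

#' Estimate base composition from a genome
#'
#' Counts A/C/G/T (other characters ignored) over all contigs.  With
#' `both_strands = TRUE` the complementary bases are averaged (A with T,
#' C with G), which is the composition of the sequence pooled with its
#' reverse complement.  Probabilities of exactly zero are floored at
#' `floor` and the vector renormalized, with a warning, so downstream
#' log-odds stay finite.
#'
#' @param genome A genome tibble from [read_genome()], a character vector
#'   of sequences, or a single DNA string.
#' @param both_strands Average complementary base frequencies.
#' @param floor Lower bound applied to zero probabilities.
#' @return A `background_model`.
#' @export
estimate_background <- function(genome, both_strands = FALSE, floor = 1e-6) {
  seqs <- if (is.data.frame(genome)) genome$sequence else genome
  if (length(seqs) == 0L) stop_invalid("Genome has no sequences.")
  set <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- colSums(Biostrings::letterFrequency(set, DNA_BASES))
  total <- sum(counts)
  if (total == 0) stop_invalid("Genome contains no A/C/G/T bases.")
  p <- counts / total
  if (both_strands) {
    p <- c(A = (p[["A"]] + p[["T"]]) / 2, C = (p[["C"]] + p[["G"]]) / 2,
           G = (p[["C"]] + p[["G"]]) / 2, T = (p[["A"]] + p[["T"]]) / 2)
  }
  if (any(p == 0)) {
    warn(sprintf("Background probabilities of zero floored at %g and renormalized.", floor))
    p <- pmax(p, floor)
    p <- p / sum(p)
  }
  structure(stats::setNames(as.numeric(p), DNA_BASES), class = "background_model")
}

#' Build a log-odds scoring matrix in bits
#'
#' `w[b,i] = log2(f[b,i] / p_b)`: the score of a k-mer is the sum of its
#' per-position entries, so a sequence drawn exactly from the background
#' scores 0 in expectation at a background-matching column.
#'
#' @param freqs A `frequency_matrix` (see [to_frequencies()]).
#' @param background A `background_model`; default uniform.
#' @param on_zero `"allow"` lets zero frequencies become `-Inf` scores;
#'   `"error"` rejects them (strict policy for pseudocount-0 matrices).
#' @return A `pssm` object: list with the 4 x k score matrix `w`, the
#'   `background`, the motif width `k`, and the training `freq` matrix.
#' @export
build_pssm <- function(freqs, background = uniform_background(),
                       on_zero = c("allow", "error")) {
  on_zero <- match.arg(on_zero)
  f <- unclass(freqs)
  if (nrow(f) != 4L) stop_invalid("Frequency matrix must have 4 rows (A, C, G, T).")
  if (is.null(rownames(f))) rownames(f) <- DNA_BASES
  bad <- abs(colSums(f) - 1) > 1e-6
  if (any(bad)) {
    stop_invalid(sprintf("Frequency matrix column %d does not sum to 1.", which(bad)[1]))
  }
  p <- as.numeric(background)[match(rownames(f), DNA_BASES)]
  if (on_zero == "error" && any(f == 0)) {
    stop_invalid("Zero frequencies present; use a positive pseudocount or on_zero = \"allow\".")
  }
  w <- log2(f / p)
  dimnames(w) <- list(DNA_BASES, NULL)
  structure(list(w = w, background = background, k = ncol(w),
                 freq = if (inherits(freqs, "frequency_matrix")) freqs else NULL,
                 n_sites = attr(freqs, "n_sites"),
                 pseudocount = attr(freqs, "pseudocount")),
            class = "pssm")
}

#' Wrap a pre-built score matrix as a PSSM
#'
#' For matrices loaded from TSV (e.g. a published supplementary matrix)
#' where the underlying frequencies are unknown.
#'
#' @param w 4 x k numeric matrix of scores in bits (rows A, C, G, T).
#' @param background Optional `background_model` to record alongside.
#' @return A `pssm`.
#' @export
pssm_from_matrix <- function(w, background = NULL) {
  if (nrow(w) != 4L) stop_invalid("Score matrix must have 4 rows (A, C, G, T).")
  if (!is.null(rownames(w))) w <- w[DNA_BASES, , drop = FALSE]
  rownames(w) <- DNA_BASES
  structure(list(w = w, background = background, k = ncol(w),
                 freq = NULL, n_sites = NULL, pseudocount = NULL),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cons <- consensus_sequence(x)
  cat(sprintf("<pssm> width %d, consensus %s (%.2f bits)\n",
              x$k, cons$sequence, cons$score))
  if (!is.null(x$n_sites)) cat(sprintf("  trained on %d sites, pseudocount %g\n",
                                       x$n_sites, x$pseudocount))
  invisible(x)
}

#' Score k-mers under a PSSM
#'
#' The score of a sequence is the sum over positions of the matrix entry
#' for its base — additivity is the model's defining assumption.
#'
#' @param pssm A `pssm`.
#' @param seq Character vector of sequences, each of the motif width,
#'   A/C/G/T only.
#' @return Numeric vector of scores in bits.
#' @export
score_kmer <- function(pssm, seq) {
  seq <- toupper(seq)
  k <- pssm$k
  vapply(seq, function(s) {
    if (nchar(s) != k) {
      stop_invalid(sprintf("Sequence %s has length %d; the matrix expects %d.",
                           s, nchar(s), k))
    }
    code <- dna_code(s)
    if (anyNA(code)) stop_invalid(sprintf("Sequence %s contains non-A/C/G/T characters.", s))
    sum(pssm$w[cbind(code, seq_len(k))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Highest-scoring sequence under a PSSM
#'
#' Picks the best base at every position (valid because scores are
#' additive).  Ties are broken lexicographically A < C < G < T.
#'
#' @param pssm A `pssm`.
#' @return A list with `sequence` and its `score` in bits.
#' @export
consensus_sequence <- function(pssm) {
  best <- apply(pssm$w, 2, which.max)  # which.max takes the first = lexicographic
  seq <- paste(DNA_BASES[best], collapse = "")
  list(sequence = seq, score = score_kmer(pssm, seq))
}

#' Per-position information content in bits
#'
#' Relative entropy of each motif column against the background:
#' `IC_i = sum_b f[b,i] log2(f[b,i]/p_b)`, with `0 log 0 = 0`.  Under a
#' uniform background this reduces to `2 - H_i` (entropy in bits).
#'
#' @param freqs A `frequency_matrix`.
#' @param background A `background_model`; default uniform.
#' @return Numeric vector of length k; `sum()` of it is the motif's total
#'   information content.
#' @export
information_content <- function(freqs, background = uniform_background()) {
  f <- unclass(freqs)
  p <- as.numeric(background)
  terms <- f * log2(f / p)
  terms[f == 0] <- 0
  colSums(terms)
}

#' Dyad-symmetry (palindrome) analysis of a binding site
#'
#' Splits an even-length site into half-sites and reports, for each
#' position in the first half, whether its base equals the Watson-Crick
#' complement of the mirrored base in the second half — the signature of
#' operators bound by protein dimers.  The count is invariant under
#' reverse-complementing the input.
#'
#' @param seq A single DNA string of even length, A/C/G/T only.
#' @return A list of class `palindrome_report`: `sequence`, `half_width`,
#'   logical `matches` (length k/2) and their `count`.
#' @examples
#' palindrome_positions("TGAAAGCGCTTTCA")$count  # 7: a perfect 14-bp dyad
#' @export
palindrome_positions <- function(seq) {
  seq <- toupper(seq)
  if (length(seq) != 1L) stop_invalid("`seq` must be a single sequence; see palindrome_table().")
  k <- nchar(seq)
  if (k %% 2 != 0) stop_invalid(sprintf("Palindrome analysis needs an even length; %s has length %d.", seq, k))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!ch %in% DNA_BASES)) stop_invalid(sprintf("Sequence %s contains non-A/C/G/T characters.", seq))
  h <- k %/% 2L
  matches <- ch[seq_len(h)] == unname(DNA_COMPLEMENT[ch[k + 1L - seq_len(h)]])
  structure(list(sequence = seq, half_width = h, matches = matches,
                 count = sum(matches)),
            class = "palindrome_report")
}

#' @export
print.palindrome_report <- function(x, ...) {
  h <- x$half_width
  cat(sprintf("%s|%s  %d/%d palindrome positions (%s)\n",
              substr(x$sequence, 1, h), substr(x$sequence, h + 1, 2 * h),
              x$count, h, paste(ifelse(x$matches, "*", "."), collapse = "")))
  invisible(x)
}

#' Palindrome analysis over many sequences
#'
#' @param seqs Character vector (or tibble with a `site` or `sequence`
#'   column) of even-length DNA strings.
#' @return A tibble with `sequence`, `half_width`, `count` and a `mask`
#'   string (`*` = complementary pair, `.` = not).
#' @export
palindrome_table <- function(seqs) {
  if (is.data.frame(seqs)) {
    col <- intersect(c("site", "sequence"), names(seqs))[1]
    if (is.na(col)) stop_invalid("Data frame needs a `site` or `sequence` column.")
    seqs <- seqs[[col]]
  }
  purrr::map_dfr(seqs, function(s) {
    r <- palindrome_positions(s)
    tibble(sequence = r$sequence, half_width = r$half_width, count = r$count,
           mask = paste(ifelse(r$matches, "*", "."), collapse = ""))
  })
}

#' Match sequences against an IUPAC degenerate pattern
#'
#' A position matches when the base belongs to the expansion of the
#' pattern's code (N = any, W = A/T, S = C/G, ...).
#'
#' @param seq Character vector of A/C/G/T sequences.
#' @param pattern A single IUPAC string of the same length.
#' @return A tibble with `sequence`, `pattern`, logical `match` (all
#'   positions agree) and integer `mismatches`.
#' @examples
#' degenerate_match("TGAACGCGCGTACA", "TGNAANCGNWNNCW")
#' @export
degenerate_match <- function(seq, pattern) {
  pattern <- toupper(pattern)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(pat, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop_invalid(sprintf("Invalid IUPAC code in pattern: %s", bad[1]))
  }
  purrr::map_dfr(toupper(seq), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(ch) != length(pat)) {
      stop_invalid(sprintf("Sequence %s and pattern %s differ in length.", s, pattern))
    }
    if (any(!ch %in% DNA_BASES)) {
      stop_invalid(sprintf("Sequence %s contains non-A/C/G/T characters.", s))
    }
    ok <- purrr::map2_lgl(ch, pat, function(b, p) b %in% IUPAC_CODES[[p]])
    tibble(sequence = s, pattern = pattern,
           match = all(ok), mismatches = sum(!ok))
  })
}
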