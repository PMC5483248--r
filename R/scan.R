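# Genome scanning: score every k-mer window, stream summary statistics,
# threshold into a hit table.

#' Read genome sequences from FASTA
#'
#' @param path FASTA file with one or more DNA records.
#' @return A tibble with columns `id` (header up to the first whitespace),
#'   `sequence` (uppercased) and `length`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop_invalid(sprintf("Cannot parse FASTA %s: %s",
                                                           path, conditionMessage(e))))
  if (length(set) == 0L) stop_invalid(sprintf("FASTA file has no records: %s", path))
  seqs <- toupper(as.character(set))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    stop_invalid("RNA (U) records are not supported; supply DNA sequences.")
  }
  seqs <- unname(seqs)
  tibble(id = sub("\\s.*$", "", names(set)),
         sequence = seqs,
         length = nchar(seqs))
}

#' Write genome sequences to FASTA
#'
#' @param genome Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Streaming (Welford/Chan) aggregate of mean and variance: chunks are
# reduced into (n, mean, M2) without keeping scores resident.
wf_empty <- function() list(n = 0, mean = 0, m2 = 0, min = Inf, max = -Inf)
wf_add <- function(st, x) {
  nb <- length(x)
  if (nb == 0L) return(st)
  mb <- mean(x)
  m2b <- sum((x - mb)^2)
  if (st$n == 0) {
    list(n = nb, mean = mb, m2 = m2b, min = min(x), max = max(x))
  } else {
    d <- mb - st$mean
    n <- st$n + nb
    list(n = n,
         mean = st$mean + d * nb / n,
         m2 = st$m2 + m2b + d^2 * st$n * nb / n,
         min = min(st$min, min(x)), max = max(st$max, max(x)))
  }
}
wf_stats <- function(st) {
  if (st$n == 0) return(list(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_))
  list(mean = st$mean,
       sd = if (st$n > 1) sqrt(st$m2 / (st$n - 1)) else NA_real_,
       min = st$min, max = st$max)
}

# Score windows starting at `starts` of an integer-coded sequence under a
# 4 x k matrix; windows containing an ambiguous base come back NA.
score_windows_at <- function(code, w, starts) {
  k <- ncol(w)
  m <- length(starts)
  if (m == 0L) return(numeric(0))
  idx <- rep.int(starts, k) + rep(0:(k - 1L), each = m)
  sc <- w[cbind(code[idx], rep(seq_len(k), each = m))]
  dim(sc) <- c(m, k)
  rowSums(sc)
}

# Score matrix for the minus strand at identical forward coordinates:
# score of revcomp(window) under w == score of window under w_rc.
revcomp_matrix <- function(w) {
  w_rc <- w[4:1, rev(seq_len(ncol(w))), drop = FALSE]
  rownames(w_rc) <- DNA_BASES
  w_rc
}

#' Scan a genome with a PSSM
#'
#' Scores every k-mer window of every contig.  Windows containing a
#' non-A/C/G/T base are skipped and counted.  In `"both"` strand mode the
#' reverse complement of each window is scored as well and, by default,
#' only the better strand is emitted per position (`emit = "both"` keeps
#' both).  Summary statistics are accumulated in a single streaming pass
#' (numerically stable chunked mean/variance), so only the emitted window
#' table — not any intermediate score vector — scales with genome size.
#'
#' @param genome Genome tibble from [read_genome()] / [synth_genome()], or
#'   a character vector of sequences.
#' @param pssm A `pssm`.
#' @param strand_mode `"forward"` (default; one window per start position)
#'   or `"both"`.
#' @param emit In `"both"` mode, `"best"` keeps the higher-scoring strand
#'   per position, `"both"` keeps both strands.
#' @param return_windows Set `FALSE` to collect only the summary (the
#'   window tibble comes back empty); useful for very large genomes.
#' @param chunk_size Windows scored per streaming chunk.
#' @return A tibble of class `scan_result` with columns `contig`, `start`,
#'   `end` (1-based, inclusive), `strand`, `score`; the `ScanSummary`
#'   (windows scored/skipped, mean, sd, min, max) is attached as attribute
#'   `summary` and available via [scan_summary()] or [glance()].
#' @export
scan_genome <- function(genome, pssm, strand_mode = c("forward", "both"),
                        emit = c("best", "both"), return_windows = TRUE,
                        chunk_size = 200000L) {
  strand_mode <- match.arg(strand_mode)
  emit <- match.arg(emit)
  if (!is.data.frame(genome)) {
    genome <- tibble(id = sprintf("seq_%d", seq_along(genome)),
                     sequence = toupper(genome), length = nchar(genome))
  }
  k <- pssm$k
  w <- pssm$w
  w_rc <- revcomp_matrix(w)

  usable <- genome$length >= k
  if (!all(usable)) {
    warn(sprintf("%d contig(s) shorter than the motif width (%d) excluded from the scan.",
                 sum(!usable), k))
  }
  if (!any(usable)) stop_invalid(sprintf("No contig is at least %d bases long.", k))

  st <- wf_empty()
  n_skipped <- 0L
  pieces <- list()

  for (ci in which(usable)) {
    code <- dna_code(genome$sequence[ci])
    L <- genome$length[ci]
    n_win <- L - k + 1L
    for (from in seq(1L, n_win, by = chunk_size)) {
      starts <- from:min(from + chunk_size - 1L, n_win)
      fwd <- score_windows_at(code, w, starts)
      if (strand_mode == "forward") {
        ok <- !is.na(fwd)
        n_skipped <- n_skipped + sum(!ok)
        sc <- fwd[ok]
        st <- wf_add(st, sc)
        if (return_windows && length(sc) > 0L) {
          pieces[[length(pieces) + 1L]] <- tibble(
            contig = genome$id[ci], start = starts[ok], end = starts[ok] + k - 1L,
            strand = "+", score = sc)
        }
      } else {
        rev <- score_windows_at(code, w_rc, starts)
        ok <- !is.na(fwd)  # ambiguity is strand-independent
        n_skipped <- n_skipped + sum(!ok)
        if (emit == "best") {
          strand <- ifelse(rev[ok] > fwd[ok], "-", "+")
          sc <- pmax(fwd[ok], rev[ok])
          st <- wf_add(st, sc)
          if (return_windows && length(sc) > 0L) {
            pieces[[length(pieces) + 1L]] <- tibble(
              contig = genome$id[ci], start = starts[ok], end = starts[ok] + k - 1L,
              strand = strand, score = sc)
          }
        } else {
          sc <- c(fwd[ok], rev[ok])
          st <- wf_add(st, sc)
          if (return_windows && length(sc) > 0L) {
            pieces[[length(pieces) + 1L]] <- tibble(
              contig = genome$id[ci],
              start = c(starts[ok], starts[ok]), end = c(starts[ok], starts[ok]) + k - 1L,
              strand = rep(c("+", "-"), each = sum(ok)), score = sc)
          }
        }
      }
    }
  }

  windows <- if (length(pieces) > 0L) dplyr::bind_rows(pieces) else
    tibble(contig = character(), start = integer(), end = integer(),
           strand = character(), score = numeric())
  s <- wf_stats(st)
  summary <- tibble(n_scored = as.integer(st$n), n_skipped = n_skipped,
                    mean = s$mean, sd = s$sd, min = s$min, max = s$max)
  structure(windows, summary = summary, k = k, strand_mode = strand_mode,
            class = c("scan_result", class(windows)))
}

#' Summary statistics of a genome scan
#'
#' @param x A `scan_result` from [scan_genome()].
#' @return One-row tibble: windows scored, windows skipped (ambiguous
#'   bases), mean, sd, min and max score in bits.
#' @export
scan_summary <- function(x) {
  s <- attr(x, "summary")
  if (is.null(s)) stop_invalid("Not a scan result: no summary attribute.")
  s
}

#' Threshold scan windows into a hit table
#'
#' @param windows A `scan_result` (or any tibble with `contig`, `start`,
#'   `end`, `strand`, `score`).
#' @param threshold Minimum score in bits; windows with `score >=
#'   threshold` are kept (ties count as detected).
#' @return Hits sorted by descending score, ties broken by contig then
#'   coordinate; class `hit_table` with the threshold attached as an
#'   attribute.
#' @export
call_hits <- function(windows, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop_invalid("`threshold` must be a single finite number.")
  }
  hits <- windows |>
    as_tibble() |>
    dplyr::filter(.data$score >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$contig, .data$start, .data$strand)
  structure(hits, threshold = threshold, class = c("hit_table", class(tibble())))
}

#' Window sequences of scan hits
#'
#' Extracts the genomic sequence under each window; minus-strand windows
#' are reverse-complemented so the returned string is the motif-oriented
#' sequence that was scored.
#'
#' @param windows Tibble with `contig`, `start`, `end`, `strand`.
#' @param genome Genome tibble with `id` and `sequence`.
#' @return Character vector, one sequence per window.
#' @export
window_sequences <- function(windows, genome) {
  seq_by_id <- stats::setNames(genome$sequence, genome$id)
  missing <- setdiff(unique(windows$contig), names(seq_by_id))
  if (length(missing) > 0L) {
    stop_invalid(sprintf("Window contig %s not present in the genome.", missing[1]))
  }
  s <- substr(seq_by_id[windows$contig], windows$start, windows$end)
  ifelse(windows$strand == "-", revcomp(s), unname(s))
}
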