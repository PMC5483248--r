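# Matrix, BED and config I/O.

#' Write a 4 x k motif matrix as TSV
#'
#' Layout: header `pos A C G T`, one row per motif position, values to six
#' decimals (non-finite entries written literally).  This is the layout
#' [read_matrix_tsv()] round-trips.
#'
#' @param mat 4 x k matrix (counts, frequencies or bit scores; rows A, C,
#'   G, T) — or a `pssm`, whose score matrix is written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (inherits(mat, "pssm")) mat <- mat$w
  m <- unclass(mat)
  if (nrow(m) != 4L) stop_invalid("Matrix must have 4 rows (A, C, G, T).")
  if (!is.null(rownames(m))) m <- m[DNA_BASES, , drop = FALSE]
  fmt <- function(x) ifelse(is.finite(x), sprintf("%.6f", x), as.character(x))
  lines <- c("pos\tA\tC\tG\tT",
             vapply(seq_len(ncol(m)),
                    function(i) paste(c(i, fmt(m[, i])), collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4 x k motif matrix from TSV
#'
#' Accepts the `pos A C G T` per-position layout written by
#' [write_matrix_tsv()], or a transposed 4-row layout (one row per base,
#' labeled A/C/G/T in the first column) — auto-detected.  `#` comment
#' lines are ignored.
#'
#' @param path TSV path.
#' @return Plain 4 x k numeric matrix with rows A, C, G, T.  Wrap with
#'   [pssm_from_matrix()] (bit scores) or [as_frequency_matrix()]
#'   (frequencies) as appropriate.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("Matrix file not found: %s", path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE, col_names = TRUE)
  nm <- toupper(names(tb))
  if (all(DNA_BASES %in% nm)) {
    m <- t(as.matrix(tb[, match(DNA_BASES, nm)]))
  } else {
    # transposed layout: one row per base, labels in the first column
    # (a non-base header row, if present, is skipped)
    tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE, col_names = FALSE)
    first <- toupper(as.character(tb[[1]]))
    tb <- tb[first %in% DNA_BASES, , drop = FALSE]
    first <- first[first %in% DNA_BASES]
    if (!setequal(first, DNA_BASES) || length(first) != 4L) {
      stop_invalid(sprintf("Unrecognized matrix layout in %s: need a `pos A C G T` header or A/C/G/T row labels.", path))
    }
    m <- as.matrix(tb[match(DNA_BASES, first), -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
  }
  if (anyNA(suppressWarnings(as.numeric(m)))) {
    stop_invalid(sprintf("Non-numeric matrix entries in %s.", path))
  }
  m <- matrix(as.numeric(m), nrow = 4L, dimnames = list(DNA_BASES, NULL))
  m
}

#' Interpret a plain matrix as column-stochastic frequencies
#'
#' @param m 4 x k matrix of probabilities (rows A, C, G, T), columns
#'   summing to 1 within 1e-6.
#' @param n_sites,pseudocount Optional provenance attributes.
#' @return A `frequency_matrix`.
#' @export
as_frequency_matrix <- function(m, n_sites = NA_integer_, pseudocount = NA_real_) {
  if (nrow(m) != 4L) stop_invalid("Frequency matrix must have 4 rows.")
  if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-6)) {
    stop_invalid("Columns must be probability distributions (sum to 1).")
  }
  rownames(m) <- DNA_BASES
  structure(m, n_sites = n_sites, pseudocount = pseudocount,
            class = c("frequency_matrix", "matrix", "array"))
}

#' Read a JASPAR-style count matrix
#'
#' Parses the common `>ID name` header followed by four lines of the form
#' `A [ 3 21 25 ... ]` (brackets optional).
#'
#' @param path JASPAR .jaspar/.pfm file; only the first record is read.
#' @return A `count_matrix`.  If column sums are unequal the site count is
#'   taken as the rounded median with a warning.
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("JASPAR file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  rows <- list()
  for (ln in lines[seq_len(min(4L, length(lines)))]) {
    base <- toupper(substr(ln, 1, 1))
    if (!base %in% DNA_BASES) stop_invalid(sprintf("Expected an A/C/G/T row, got: %s", ln))
    nums <- gsub("[][]", " ", substr(ln, 2, nchar(ln)))
    rows[[base]] <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
  }
  if (length(rows) != 4L || length(unique(lengths(rows))) != 1L) {
    stop_invalid(sprintf("Malformed JASPAR matrix in %s.", path))
  }
  counts <- do.call(rbind, rows[DNA_BASES])
  cs <- colSums(counts)
  if (length(unique(cs)) != 1L) {
    warn("JASPAR column sums are unequal; using the median as the site count.")
  }
  structure(counts, n_sites = as.integer(round(stats::median(cs))),
            class = c("count_matrix", "matrix", "array"))
}

#' Write hits as BED6
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention.  The score column carries the PSSM score in bits
#' rounded to 2 decimals (not rescaled to BED's 0-1000 range, so bit
#' values survive a round-trip).  A `#` header comment is always written,
#' so an empty hit table yields a non-empty, self-describing file, and
#' identical inputs yield byte-identical output.
#'
#' @param hits A `hit_table` (or tibble with `contig`, `start`, `end`,
#'   `strand`, `score`).
#' @param path Output path.
#' @param names Optional hit names; default `hit_1`, `hit_2`, ...
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path, names = NULL) {
  tb <- as_tibble(hits)
  if (is.null(names)) {
    names <- if (nrow(tb) > 0L) sprintf("hit_%d", seq_len(nrow(tb))) else character(0)
  }
  if (!"score" %in% names(tb)) tb$score <- 0
  if (!"strand" %in% names(tb)) tb$strand <- "+"
  header <- "#contig\tstart\tend\tname\tscore\tstrand"
  body <- if (nrow(tb) > 0L) {
    sprintf("%s\t%d\t%d\t%s\t%.2f\t%s",
            tb$contig, tb$start - 1L, tb$end, names, tb$score, tb$strand)
  } else character(0)
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a BED file back into 1-based inclusive coordinates
#'
#' @param path BED path; `#` comments and `track` lines are skipped.
#' @return Tibble with `contig`, `start`, `end` (1-based inclusive) and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  if (ncol < 3L) stop_invalid(sprintf("BED records need at least 3 columns: %s", path))
  get <- function(i) vapply(parts, `[[`, character(1), i)
  out <- tibble(contig = get(1),
                start = as.integer(get(2)) + 1L,
                end = as.integer(get(3)))
  if (ncol >= 4L) out$name <- get(4)
  if (ncol >= 5L) out$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6L) out$strand <- get(6)
  out
}

#' Resolved run configuration
#'
#' @param ... Named configuration values overriding the defaults
#'   (pseudocount, background mode, strand mode, threshold grid, upstream
#'   window, seed).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(pseudocount = 0.5, background = "genome", strand = "forward",
              thresholds = "9:19:1", upstream_window = 500, seed = 1L)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write the resolved configuration next to a run's outputs
#'
#' Flat `key=value` lines plus the package version, so every output
#' directory records how it was produced.
#'
#' @param config A `run_config` (or plain named list).
#' @param dir Output directory (created if needed).
#' @param file File name; default `run_config.txt`.
#' @return The file path, invisibly.
#' @export
write_run_config <- function(config, dir, file = "run_config.txt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, file)
  vals <- vapply(config, function(v) paste(format(v, trim = TRUE), collapse = ","),
                 character(1))
  lines <- c(sprintf("crescan_version=%s", as.character(utils::packageVersion("crescan"))),
             sprintf("%s=%s", names(config), vals))
  writeLines(lines, path)
  invisible(path)
}
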