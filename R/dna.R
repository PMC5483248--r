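# DNA alphabet helpers shared across the package.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# IUPAC ambiguity codes -> the set of bases each one stands for.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Integer-encode a DNA string: A=1, C=2, G=3, T=4, anything else NA.
dna_code <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`; ambiguity codes other than A/C/G/T are complemented
#' per the IUPAC convention.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TGAAAGCGCTTTCA")
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTRYKMBDHVacgtrykmbdhv",
                    "TGCAYRMKVHDBtgcayrmkvhdb", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Coerce the tidy site-table / character-vector duality to a validated
# character vector of uppercase, equal-width, pure-ACGT sites.
as_site_vector <- function(sites, arg = "sites") {
  if (is.data.frame(sites)) {
    if (!"site" %in% names(sites)) {
      stop_invalid(sprintf("`%s` data frame must have a `site` column.", arg))
    }
    sites <- sites$site
  }
  if (!is.character(sites)) {
    stop_invalid(sprintf("`%s` must be a character vector or a data frame with a `site` column.", arg))
  }
  if (length(sites) == 0L) {
    stop_invalid(sprintf("`%s` is empty: at least one binding site is required.", arg))
  }
  sites <- toupper(sites)
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop_invalid(sprintf(
      "All sites must share one width: site %d has width %d, site 1 has width %d.",
      bad, widths[bad], widths[1]))
  }
  if (widths[1] < 2L) {
    stop_invalid("Motif width must be at least 2.")
  }
  bad <- which(grepl("[^ACGT]", sites))
  if (length(bad) > 0L) {
    stop_invalid(sprintf(
      "Training sites must contain only A/C/G/T: site %d (%s) has other characters.",
      bad[1], sites[bad[1]]))
  }
  sites
}

#' Read a collection of aligned binding sites
#'
#' Accepts either FASTA or plain text with one site per line (blank lines
#' and `#` comments ignored).  Sites are uppercased and validated: equal
#' width, A/C/G/T only.
#'
#' @param path Path to the site file.
#' @return A tibble with columns `name` and `site`; the motif width is
#'   attached as attribute `width`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("Site file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop_invalid(sprintf("Site file is empty: %s", path))
  if (startsWith(trimws(nonblank[1]), ">")) {
    set <- Biostrings::readDNAStringSet(path)
    out <- tibble(name = names(set), site = unname(toupper(as.character(set))))
  } else {
    keep <- nonblank[!startsWith(trimws(nonblank), "#")]
    if (length(keep) == 0L) stop_invalid(sprintf("No sites left after comments: %s", path))
    out <- tibble(name = sprintf("site_%03d", seq_along(keep)),
                  site = toupper(trimws(keep)))
  }
  out$site <- as_site_vector(out$site)
  attr(out, "width") <- nchar(out$site[1])
  out
}

#' Write a site collection as FASTA
#'
#' @param sites Tibble with `site` (and optionally `name`) columns, or a
#'   character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_fasta <- function(sites, path) {
  nm <- if (is.data.frame(sites) && "name" %in% names(sites)) sites$name else NULL
  s <- as_site_vector(sites)
  if (is.null(nm)) nm <- sprintf("site_%03d", seq_along(s))
  set <- Biostrings::DNAStringSet(s)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
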