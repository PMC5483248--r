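# Genomic-context annotation of hits against a gene table.

#' Annotate hits with the overlapping or nearest downstream gene
#'
#' Each hit is labeled `"within CDS"` when it overlaps a gene span
#' (distance 0), else `"upstream"` when a gene start lies within
#' `upstream_window` bp downstream of the hit on the gene's strand
#' (distance = gap to the gene start, in bp), else `"intergenic"`.
#' For `+` strand genes "upstream of the start" means the hit ends before
#' `start`; for `-` strand genes it means the hit begins after `end`.
#'
#' @param hits A `hit_table` (or tibble with `contig`, `start`, `end`).
#' @param features Gene table: tibble with `contig`, `start`, `end`,
#'   `strand`, `name` (see [read_features()]).
#' @param upstream_window Maximum promoter-region distance in bp; default
#'   500.
#' @return The hit tibble with `gene`, `location` and `distance` columns
#'   appended.
#' @export
annotate_nearest_feature <- function(hits, features, upstream_window = 500) {
  need <- c("contig", "start", "end", "strand", "name")
  if (!all(need %in% names(features))) {
    stop_invalid(sprintf("Feature table must have columns: %s.", paste(need, collapse = ", ")))
  }
  hits_tb <- as_tibble(hits)
  if (nrow(hits_tb) > 0L &&
      !any(features$contig %in% unique(hits_tb$contig))) {
    stop_invalid("Feature table references contigs absent from the hit table (naming mismatch?).")
  }
  ann <- purrr::pmap_dfr(
    hits_tb[, c("contig", "start", "end")],
    function(contig, start, end) {
      g <- features[features$contig == contig, ]
      if (nrow(g) == 0L) {
        return(tibble(gene = NA_character_, location = "intergenic", distance = NA_real_))
      }
      ov <- g$start <= end & g$end >= start
      if (any(ov)) {
        # widest overlap wins, then leftmost gene
        olap <- pmin(g$end[ov], end) - pmax(g$start[ov], start) + 1
        pick <- which(ov)[order(-olap, g$start[ov])[1]]
        return(tibble(gene = g$name[pick], location = "within CDS", distance = 0))
      }
      d <- ifelse(g$strand == "-", start - g$end, g$start - end)
      near <- d >= 1 & d <= upstream_window
      if (any(near)) {
        pick <- which(near)[which.min(d[near])]
        return(tibble(gene = g$name[pick], location = "upstream", distance = d[pick]))
      }
      tibble(gene = NA_character_, location = "intergenic", distance = NA_real_)
    })
  dplyr::bind_cols(hits_tb, ann)
}

#' Read a gene feature table (BED or GFF3)
#'
#' BED input (0-based half-open) is converted to the package's 1-based
#' inclusive coordinates.  GFF3 is read through \pkg{rtracklayer}; the
#' feature name is taken from the `Name`, `locus_tag`, `gene` or `ID`
#' attribute, in that order.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @param gff_type Optional GFF3 `type` filter (e.g. `"gene"` or `"CDS"`);
#'   `NULL` keeps all records.
#' @return Tibble with `contig`, `start`, `end`, `strand`, `name`.
#' @export
read_features <- function(path, gff_type = c("gene", "CDS")) {
  if (!file.exists(path)) stop_invalid(sprintf("Feature file not found: %s", path))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop_invalid("Reading GFF3 requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path)
    if (!is.null(gff_type)) gr <- gr[as.character(gr$type) %in% gff_type]
    meta <- as.data.frame(gr)
    nm <- rep(NA_character_, nrow(meta))
    for (col in c("Name", "locus_tag", "gene", "ID")) {
      if (col %in% names(meta)) {
        v <- as.character(meta[[col]])
        nm <- ifelse(is.na(nm) & !is.na(v), v, nm)
      }
    }
    tibble(contig = as.character(meta$seqnames), start = meta$start,
           end = meta$end, strand = as.character(meta$strand), name = nm)
  } else {
    bed <- read_bed(path)
    tibble(contig = bed$contig, start = bed$start, end = bed$end,
           strand = bed$strand, name = bed$name)
  }
}
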