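#' Intron annotation records
#'
#' Builds a validated intron table. Coordinates are 0-based half-open
#' throughout the package; conversion to/from 1-based happens only at file
#' boundaries. `upstream_exon_start` / `downstream_exon_end` are the *outer*
#' genomic bounds of the flanking exons (the inner bounds coincide with the
#' intron's own start/end), so flanking exon lengths are
#' `start - upstream_exon_start` and `downstream_exon_end - end`.
#'
#' @param intron_id,gene_id character identifiers.
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open intron coordinates.
#' @param strand `"+"` or `"-"`.
#' @param upstream_exon_start,downstream_exon_end outer flanking-exon bounds.
#'   "Upstream" is in transcript orientation: on the minus strand the upstream
#'   exon is the one with larger genomic coordinates.
#' @return a `data.frame` of class `irtax_introns`.
#' @export
intron_records <- function(intron_id, gene_id, chrom, start, end, strand,
                           upstream_exon_start, downstream_exon_end) {
  df <- data.frame(intron_id = as.character(intron_id),
                   gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   upstream_exon_start = as.integer(upstream_exon_start),
                   downstream_exon_end = as.integer(downstream_exon_end),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$intron_id))
    stop_irtax("duplicate intron ids", "irtax_schema_error")
  if (any(df$end <= df$start))
    stop_irtax("intron end must exceed start", "irtax_format_error")
  if (!all(df$strand %in% c("+", "-")))
    stop_irtax("strand must be '+' or '-'", "irtax_format_error")
  if (any(df$upstream_exon_start > df$start) || any(df$downstream_exon_end < df$end))
    stop_irtax("flanking exon bounds inconsistent with intron coordinates",
               "irtax_format_error")
  class(df) <- c("irtax_introns", "data.frame")
  df
}

#' Read / write intron records (extended BED)
#'
#' The on-disk form is BED6 plus two columns: `chrom start end intron_id
#' score strand gene_id upstream_exon_start downstream_exon_end`, 0-based
#' half-open as standard for BED.
#'
#' @param path file path.
#' @param seed optional seed for the output header.
#' @return `read_intron_bed` returns an `irtax_introns` table.
#' @export
read_intron_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9))
    stop_irtax(sprintf("intron BED line with %d < 9 fields", min(nf)),
               "irtax_format_error")
  m <- do.call(rbind, f)
  intron_records(intron_id = m[, 4], gene_id = m[, 7], chrom = m[, 1],
                 start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                 strand = m[, 6],
                 upstream_exon_start = as.integer(m[, 8]),
                 downstream_exon_end = as.integer(m[, 9]))
}

#' @rdname read_intron_bed
#' @param introns an `irtax_introns` table.
#' @export
write_intron_bed <- function(introns, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%d\t%d",
                     introns$chrom, introns$start, introns$end,
                     introns$intron_id, introns$strand, introns$gene_id,
                     introns$upstream_exon_start, introns$downstream_exon_end),
             con)
  invisible(path)
}

#' Cross-link track: single-nucleotide protein-RNA contact events for one RBP
#'
#' @param rbp_name RBP identifier.
#' @param chrom,position,strand event coordinates (0-based positions).
#'   Duplicate `(chrom, position, strand)` triples are collapsed.
#' @return a `data.frame` of class `irtax_crosslinks` with attribute
#'   `"rbp_name"`.
#' @export
crosslink_track <- function(rbp_name, chrom, position, strand) {
  df <- unique(data.frame(chrom = as.character(chrom),
                          position = as.integer(position),
                          strand = as.character(strand),
                          stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rbp_name") <- as.character(rbp_name)
  class(df) <- c("irtax_crosslinks", "data.frame")
  df
}

#' Read cross-link events from BED
#'
#' Each BED interval contributes its start coordinate as one single-nucleotide
#' cross-link event (iCLIP/eCLIP peaks collapse to 1 nt); duplicate events are
#' collapsed.
#'
#' @param path BED file (0-based half-open).
#' @param rbp_name name to attach to the track.
#' @return an `irtax_crosslinks` track.
#' @export
read_crosslink_bed <- function(path, rbp_name) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) > 0 && any(GenomicRanges::width(gr) < 1))
    stop_irtax("BED interval with end <= start", "irtax_format_error")
  crosslink_track(rbp_name,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  position = GenomicRanges::start(gr) - 1L,
                  strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_crosslink_bed
#' @param track an `irtax_crosslinks` track to write (1-nt BED intervals).
#' @param seed optional seed for the output header.
#' @export
write_crosslink_bed <- function(track, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  if (nrow(track) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", track$chrom, track$position,
                       track$position + 1L, attr(track, "rbp_name"),
                       track$strand), con)
  invisible(path)
}

#' Read / write miRNA target sets (GMT)
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a line are collapsed; empty sets are rejected.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (one element per target set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3))
    stop_irtax("GMT line with fewer than 3 fields", "irtax_format_error")
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  if (any(lengths(sets) == 0))
    stop_irtax("empty target set in GMT", "irtax_format_error")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("irtax", length(sets))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sets)) {
    writeLines(paste(c(names(sets)[i], descriptions[i], sets[[i]]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a differential-expression table
#'
#' One row per gene per contrast, with `gene_id`, `log2fc`, `p_value` and
#' `contrast_label` columns; p-values must lie in `(0, 1]`.
#'
#' @param path TSV path.
#' @return a `data.frame`.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("gene_id", "log2fc", "p_value", "contrast_label")
  if (!all(need %in% names(df)))
    stop_irtax(paste("DE table missing columns:",
                     paste(setdiff(need, names(df)), collapse = ", ")),
               "irtax_schema_error")
  if (any(!is.na(df$p_value) & (df$p_value <= 0 | df$p_value > 1)))
    stop_irtax("p_value outside (0,1]", "irtax_range_error")
  if (anyDuplicated(df[, c("gene_id", "contrast_label")]))
    stop_irtax("duplicate (gene, contrast) rows in DE table", "irtax_schema_error")
  df
}

#' @rdname read_de_table
#' @param de DE `data.frame` to write.
#' @param seed optional seed for the output header.
#' @export
write_de_table <- function(de, path, seed = NULL) {
  write_tsv_commented(de[, c("gene_id", "log2fc", "p_value", "contrast_label")],
                      path, seed = seed)
}

#' Read a per-base conservation track (bedGraph)
#'
#' @param path bedGraph file (0-based half-open intervals with a score).
#' @return a `GRanges` with a `score` metadata column.
#' @export
read_conservation_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Read / write sequences (FASTA)
#'
#' Thin wrappers around Biostrings so callers stay within the package surface.
#' @param path FASTA path.
#' @return `read_sequences` returns a named `DNAStringSet`.
#' @export
read_sequences <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_sequences
#' @param seqs named character vector or `DNAStringSet`.
#' @export
write_sequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
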