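#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator
#' and denominator. Strand-invariant (G+C is preserved under reverse
#' complement).
#'
#' @param sequence a single A/C/G/T/N string (case-insensitive).
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  if (!nzchar(sequence))
    stop_irtax("empty sequence", "irtax_data_error")
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "N")))
    stop_irtax("sequence contains non-ACGTN characters", "irtax_format_error")
  denom <- sum(ch != "N")
  if (denom == 0)
    stop_irtax("all-N sequence: GC undefined", "irtax_undefined_feature")
  sum(ch %in% c("G", "C")) / denom
}

#' Median per-base conservation score over an interval
#'
#' Expands the track's intervals to per-base scores over the query interval
#' and takes their median. The interval must be covered on at least half of
#' its bases, else the feature is undefined.
#'
#' @param track `GRanges` with a `score` column (e.g. from
#'   [read_conservation_bedgraph()]).
#' @param chrom,start,end query interval, 0-based half-open.
#' @param min_coverage minimum covered fraction (default 0.5).
#' @return median score (numeric scalar).
#' @export
median_conservation <- function(track, chrom, start, end, min_coverage = 0.5) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(track, q, ignore.strand = TRUE)
  if (length(hits) == 0)
    stop_irtax("no conservation data over interval", "irtax_undefined_feature")
  sub <- track[S4Vectors::queryHits(hits)]
  lo <- pmax(GenomicRanges::start(sub), start + 1L)
  hi <- pmin(GenomicRanges::end(sub), end)
  scores <- rep(sub$score, hi - lo + 1L)
  if (length(scores) < min_coverage * (end - start))
    stop_irtax("interval covered on fewer than half of its bases",
               "irtax_undefined_feature")
  stats::median(scores)
}

#' Scan an intron-retaining transcript for premature termination codons
#'
#' Builds the retained transcript (exons in transcript order with the intron
#' inserted after exon `intron_after`), translates in-frame from `cds_start`
#' and applies the 50-nt rule: a stop codon is premature when it lies more
#' than 50 nt upstream of the final exon-exon junction of the retained
#' transcript. Only the annotated reading frame is scanned; translation
#' terminates at the first in-frame stop, and `has_ptc` reports whether that
#' stop is premature. The retained intron's own boundaries are not junctions
#' (no splicing occurred there); if the transcript has no remaining
#' exon-exon junction no stop can be premature.
#'
#' @param exon_seqs character vector of exon sequences in transcript order.
#' @param intron_seq retained intron sequence.
#' @param intron_after index of the exon after which the intron sits.
#' @param cds_start 1-based position of the start codon in the *retained*
#'   transcript; must point at `ATG`.
#' @return list with `has_ptc`, `ptc_positions` (1-based start positions of
#'   premature stops up to and including the terminating one), `stop_position`
#'   (first in-frame stop, `NA` if none) and `last_junction` (position of the
#'   last transcribed exon-exon junction, `NA` if none).
#' @export
ptc_scan <- function(exon_seqs, intron_seq, intron_after, cds_start) {
  n_ex <- length(exon_seqs)
  if (intron_after < 1 || intron_after >= n_ex)
    stop_irtax("intron_after must name an internal exon boundary",
               "irtax_annotation_error")
  pieces <- append(exon_seqs, intron_seq, after = intron_after)
  tx <- toupper(paste(pieces, collapse = ""))
  if (cds_start < 1 || cds_start + 2 > nchar(tx) ||
      substr(tx, cds_start, cds_start + 2) != "ATG")
    stop_irtax("CDS start not found (no ATG at cds_start)",
               "irtax_annotation_error")

  # exon-exon junction positions (last base of the upstream exon) in
  # retained-transcript coordinates; the retained boundary is not a junction
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  junctions <- integer(0)
  for (j in seq_len(n_ex - 1)) {
    if (j == intron_after) next
    piece_idx <- if (j <= intron_after) j else j + 1L  # account for intron piece
    junctions <- c(junctions, ends[piece_idx])
  }
  last_junction <- if (length(junctions)) max(junctions) else NA_integer_

  starts <- seq(cds_start, nchar(tx) - 2, by = 3)
  codons <- substring(tx, starts, starts + 2)
  stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
  is_premature <- function(pos) {
    !is.na(last_junction) && (last_junction - (pos + 2L)) > 50L
  }
  if (length(stop_idx) == 0) {
    return(list(has_ptc = FALSE, ptc_positions = integer(0),
                stop_position = NA_integer_, last_junction = last_junction))
  }
  first_stop <- starts[stop_idx[1]]
  ptc <- starts[stop_idx][vapply(starts[stop_idx], is_premature, logical(1))]
  ptc <- ptc[ptc <= first_stop]
  list(has_ptc = is_premature(first_stop), ptc_positions = as.integer(ptc),
       stop_position = as.integer(first_stop), last_junction = last_junction)
}

#' Assemble the per-intron feature table
#'
#' Computes the characteristic features the retention level is modelled on:
#' intron length (as `log10(length)` by default, or the literal
#' `logit(length / max_length)` behind a flag), GC content, median
#' conservation, the per-intron cross-link enrichment and the number of
#' introns in the host gene. Optional precomputed splice-site
#' maximum-entropy scores may be joined in as extra columns.
#'
#' @param introns `irtax_introns` for the focal introns.
#' @param sequences named character vector of chromosome sequences.
#' @param all_introns `irtax_introns` for all introns (to count introns per
#'   gene); defaults to `introns`.
#' @param conservation optional `GRanges` conservation track.
#' @param rbp_enrichment optional named numeric (per-intron enrichment).
#' @param splice_scores optional data.frame `intron_id`, `splice5_score`,
#'   `splice3_score`.
#' @param length_transform `"log10"` (default) or `"logit"`.
#' @return data.frame of per-intron features; introns with undefined
#'   features carry `NA` in that column.
#' @export
intron_feature_table <- function(introns, sequences, all_introns = introns,
                                 conservation = NULL, rbp_enrichment = NULL,
                                 splice_scores = NULL,
                                 length_transform = c("log10", "logit")) {
  length_transform <- match.arg(length_transform)
  len <- introns$end - introns$start
  length_feat <- if (length_transform == "log10") {
    log10(len)
  } else {
    p <- len / (max(len) + 1)
    log(p / (1 - p))
  }
  gc <- vapply(seq_len(nrow(introns)), function(i) {
    s <- substr(sequences[[introns$chrom[i]]], introns$start[i] + 1L, introns$end[i])
    gc_content(s)
  }, numeric(1))
  n_in_gene <- table(all_introns$gene_id)
  cons <- rep(NA_real_, nrow(introns))
  if (!is.null(conservation)) {
    for (i in seq_len(nrow(introns))) {
      cons[i] <- tryCatch(
        median_conservation(conservation, introns$chrom[i], introns$start[i],
                            introns$end[i]),
        irtax_undefined_feature = function(e) NA_real_)
    }
  }
  out <- data.frame(intron_id = introns$intron_id,
                    gene_id = introns$gene_id,
                    length_nt = len, length_feature = length_feat, gc = gc,
                    conservation_median = cons,
                    n_introns_in_gene = as.integer(n_in_gene[introns$gene_id]),
                    rbp_enrichment = if (is.null(rbp_enrichment)) NA_real_
                                     else unname(rbp_enrichment[introns$intron_id]),
                    stringsAsFactors = FALSE)
  if (!is.null(splice_scores)) out <- merge(out, splice_scores, by = "intron_id",
                                            all.x = TRUE, sort = FALSE)
  out
}

#' Nested-model ANOVA of PIR on intron features
#'
#' Fits an ordinary least squares model of the response (typically the
#' maximum PIR per intron across samples of one compartment) on all
#' standardized features; each feature's contribution is tested by comparing
#' against the reduced model without it:
#' `F = ((RSS_red - RSS_full) / d_df) / (RSS_full / df_den)`.
#'
#' @param features data.frame of feature columns (complete rows only are
#'   used; >= 20 required).
#' @param response numeric response aligned with `features` rows.
#' @param feature_cols character, which columns of `features` to use.
#' @return data.frame `feature_name`, `f_statistic`, `p_value`, `df_num`,
#'   `df_den`.
#' @export
pir_feature_anova <- function(features, response,
                              feature_cols = c("length_feature", "gc",
                                               "conservation_median",
                                               "rbp_enrichment",
                                               "n_introns_in_gene")) {
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  ok <- stats::complete.cases(x) & is.finite(response)
  x <- x[ok, , drop = FALSE]
  y <- response[ok]
  if (nrow(x) < 20)
    stop_irtax("need >= 20 complete rows for the feature ANOVA", "irtax_data_error")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_irtax(sprintf("degenerate feature (constant): %s",
                       paste(feature_cols[sds == 0], collapse = ", ")),
               "irtax_collinearity_error")
  x <- scale(x)
  kap <- kappa(crossprod(cbind(1, x)), exact = TRUE)
  if (kap > 1e8) {
    cc <- stats::cor(x)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop_irtax(sprintf("collinear features: %s vs %s",
                       feature_cols[worst[1]], feature_cols[worst[2]]),
               "irtax_collinearity_error")
  }
  dat <- data.frame(y = y, x)
  full <- stats::lm(y ~ ., data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  df_den <- stats::df.residual(full)
  out <- lapply(seq_along(feature_cols), function(j) {
    red <- stats::lm(y ~ ., data = dat[, -(j + 1), drop = FALSE])
    rss_red <- sum(stats::residuals(red)^2)
    d_df <- stats::df.residual(red) - df_den
    f <- ((rss_red - rss_full) / d_df) / (rss_full / df_den)
    data.frame(feature_name = feature_cols[j], f_statistic = f,
               p_value = stats::pf(f, d_df, df_den, lower.tail = FALSE),
               df_num = d_df, df_den = df_den, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Maximum PIR per intron within one compartment
#'
#' @param pir an `irtax_pir`.
#' @param fraction compartment to summarize.
#' @return named numeric vector of per-intron maxima (`NA` if all missing).
#' @export
max_pir <- function(pir, fraction = "nucleus") {
  sub <- pir_subset(pir, fraction = fraction)
  mx <- suppressWarnings(apply(sub$values, 1, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- NA_real_
  mx
}
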