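# Five 30-nt regions anchored at the splice sites, in transcript
# orientation: R1 = last 30 nt of the upstream exon, R2 = first 30 nt of the
# intron, R3 = 30 nt centered on the intron midpoint, R4 = last 30 nt of the
# intron, R5 = first 30 nt of the downstream exon.

REGION_WIDTH <- 30L
MIN_REGIONAL_INTRON <- 91L  # below this R2/R3/R4 would overlap

#' Define the five splice-site-anchored regions for each intron
#'
#' Strand-aware: on the minus strand the upstream exon is the one with larger
#' genomic coordinates and the regions mirror accordingly. R3 is the 30-nt
#' window centered on `floor((start + end) / 2)`. Regions are flagged
#' invalid (never an error) when the intron is shorter than 91 nt (the three
#' intronic windows would overlap: R2/R3/R4 invalid) or a flanking exon is
#' shorter than 30 nt (R1 or R5 invalid).
#'
#' @param introns an `irtax_introns` table.
#' @return data.frame in long form: `intron_id`, `region` (R1..R5), `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `valid`.
#' @export
define_regions <- function(introns) {
  w <- REGION_WIDTH
  mid <- (introns$start + introns$end) %/% 2L
  plus <- introns$strand == "+"
  up_len <- introns$start - introns$upstream_exon_start
  down_len <- introns$downstream_exon_end - introns$end
  # exon lengths in transcript orientation
  up_ex <- ifelse(plus, up_len, down_len)
  down_ex <- ifelse(plus, down_len, up_len)
  len_ok <- (introns$end - introns$start) >= MIN_REGIONAL_INTRON

  reg <- function(region, start, end, valid) {
    data.frame(intron_id = introns$intron_id, region = region,
               chrom = introns$chrom, start = as.integer(start),
               end = as.integer(end), strand = introns$strand,
               valid = valid, stringsAsFactors = FALSE)
  }
  out <- rbind(
    reg("R1", ifelse(plus, introns$start - w, introns$end),
        ifelse(plus, introns$start, introns$end + w), up_ex >= w),
    reg("R2", ifelse(plus, introns$start, introns$end - w),
        ifelse(plus, introns$start + w, introns$end), len_ok),
    reg("R3", mid - w %/% 2L, mid + w %/% 2L, len_ok),
    reg("R4", ifelse(plus, introns$end - w, introns$start),
        ifelse(plus, introns$end, introns$start + w), len_ok),
    reg("R5", ifelse(plus, introns$end, introns$start - w),
        ifelse(plus, introns$end + w, introns$start), down_ex >= w))
  out[order(match(out$intron_id, introns$intron_id), out$region), ,
      drop = FALSE]
}

#' Build the cross-link hit matrix
#'
#' For every (intron, RBP) pair, whether each valid region carries at least
#' one strand-matched cross-link event, whether the whole intron does
#' (events anywhere in `[start, end)`, independent of the 30-nt windows),
#' and the whole-intron event count. Events on chromosomes absent from the
#' intron annotation are skipped with a warning.
#'
#' @param tracks named list of `irtax_crosslinks` tracks.
#' @param regions output of [define_regions()] for `introns`.
#' @param introns the `irtax_introns` table.
#' @return list of class `irtax_hits`: `hits` (introns x RBPs x scopes
#'   logical array, scopes R1..R5 plus `intron`; invalid regions are `NA`),
#'   `counts` (introns x RBPs whole-intron event counts), `n_skipped`.
#' @export
build_hit_matrix <- function(tracks, regions, introns) {
  scopes <- c("R1", "R2", "R3", "R4", "R5", "intron")
  rbps <- vapply(tracks, attr, "", "rbp_name")
  hits <- array(NA, dim = c(nrow(introns), length(tracks), length(scopes)),
                dimnames = list(introns$intron_id, rbps, scopes))
  counts <- matrix(0L, nrow(introns), length(tracks),
                   dimnames = list(introns$intron_id, rbps))
  known <- unique(introns$chrom)
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L, regions$end),
                                   strand = regions$strand)
  int_gr <- GenomicRanges::GRanges(introns$chrom,
                                   IRanges::IRanges(introns$start + 1L, introns$end),
                                   strand = introns$strand)
  ridx <- match(regions$intron_id, introns$intron_id)
  rsc <- match(regions$region, scopes)
  n_skipped <- 0L
  for (t in seq_along(tracks)) {
    tr <- tracks[[t]]
    bad <- !(tr$chrom %in% known)
    if (any(bad)) n_skipped <- n_skipped + sum(bad)
    tr <- tr[!bad, , drop = FALSE]
    ev <- GenomicRanges::GRanges(tr$chrom,
                                 IRanges::IRanges(tr$position + 1L, width = 1L),
                                 strand = tr$strand)
    # regional hits (valid regions only)
    oh <- GenomicRanges::findOverlaps(reg_gr, ev, ignore.strand = FALSE)
    hit_reg <- unique(S4Vectors::queryHits(oh))
    for (s in seq_along(scopes)[-6]) {
      sel <- which(rsc == s)
      v <- regions$valid[sel]
      hits[ridx[sel][v], t, s] <- sel[v] %in% hit_reg
    }
    # whole-intron hits and counts
    oi <- GenomicRanges::findOverlaps(int_gr, ev, ignore.strand = FALSE)
    cnt <- tabulate(S4Vectors::queryHits(oi), nbins = nrow(introns))
    counts[, t] <- cnt
    hits[, t, "intron"] <- cnt > 0
  }
  if (n_skipped > 0)
    warning(sprintf("%d cross-link events on unknown chromosomes skipped",
                    n_skipped))
  structure(list(hits = hits, counts = counts, n_skipped = n_skipped),
            class = "irtax_hits")
}

#' Cross-link enrichment of an intron group over a background
#'
#' For each RBP and scope, the fraction of the group's (valid) regions with
#' at least one cross-link event divided by the same fraction in the
#' background set, with a one-sided (greater) Fisher's exact test on the
#' 2x2 table `{group, non-group} x {hit, miss}`. The background must contain
#' the group; a zero background fraction yields an undefined (NA) score.
#'
#' @param hits an `irtax_hits` object.
#' @param group,background character vectors of intron ids
#'   (`group` must be a subset of `background`).
#' @param scope one of `"R1"`..`"R5"`, `"intron"`.
#' @param group_label label recorded in the output.
#' @param alternative Fisher alternative (default `"greater"`; the analysis
#'   reports enrichment).
#' @return data.frame, one row per RBP: `group`, `rbp`, `scope`,
#'   `fraction_group`, `fraction_background`, `enrichment`, `p_value`,
#'   `n_group`, `n_background`.
#' @export
group_enrichment <- function(hits, group, background, scope = "intron",
                             group_label = "group",
                             alternative = "greater") {
  if (!all(group %in% background))
    stop_irtax("group must be a subset of the background", "irtax_config_error")
  h <- hits$hits[, , scope, drop = TRUE]
  if (is.null(dim(h))) h <- matrix(h, ncol = dim(hits$hits)[2],
                                   dimnames = dimnames(hits$hits)[1:2])
  out <- lapply(colnames(h), function(rb) {
    hg <- h[group, rb]
    hb <- h[background, rb]
    hg <- hg[!is.na(hg)]; hb <- hb[!is.na(hb)]
    n_g <- length(hg); n_b <- length(hb)
    fg <- if (n_g > 0) mean(hg) else NA_real_
    fb <- if (n_b > 0) mean(hb) else NA_real_
    enr <- if (!is.na(fb) && fb > 0) fg / fb else NA_real_
    # 2x2: group vs non-group (background minus group)
    k_g <- sum(hg); k_ng <- sum(hb) - k_g
    n_ng <- n_b - n_g
    p <- if (n_ng > 0) {
      stats::fisher.test(matrix(c(k_g, n_g - k_g, k_ng, n_ng - k_ng),
                                2, 2, byrow = TRUE),
                         alternative = alternative)$p.value
    } else NA_real_
    data.frame(group = group_label, rbp = rb, scope = scope,
               fraction_group = fg, fraction_background = fb,
               enrichment = enr, p_value = p, n_group = n_g,
               n_background = n_b, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Enrichment table across several groups and scopes
#'
#' Convenience wrapper running [group_enrichment()] for every (group, scope)
#' combination against a shared background.
#'
#' @param hits an `irtax_hits`.
#' @param groups named list of intron-id vectors.
#' @param background background intron ids.
#' @param scopes character vector of scopes.
#' @inheritParams group_enrichment
#' @return row-bound enrichment data.frame.
#' @export
enrichment_table <- function(hits, groups, background,
                             scopes = c("R1", "R2", "R3", "R4", "R5"),
                             alternative = "greater") {
  do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(scopes, function(sc) {
      group_enrichment(hits, groups[[g]], background, scope = sc,
                       group_label = g, alternative = alternative)
    }))
  }))
}

#' Per-intron cross-link enrichment over non-retained introns of the gene
#'
#' Length-normalized event-rate ratio: events per nucleotide in the retained
#' intron divided by the pooled events per nucleotide across the gene's
#' non-retained introns. Undefined (`NA`) when the pooled background rate is
#' zero.
#'
#' @param tracks named list of `irtax_crosslinks` (events pooled over RBPs).
#' @param intron one-row `irtax_introns` (the retained intron).
#' @param nonretained `irtax_introns` rows for the gene's non-retained
#'   introns (>= 1 required).
#' @return numeric scalar (rate ratio) or `NA`.
#' @export
per_intron_enrichment <- function(tracks, intron, nonretained) {
  if (nrow(nonretained) == 0)
    stop_irtax("gene has no non-retained introns", "irtax_undefined_feature")
  count_in <- function(rows) {
    tot <- 0L
    for (tr in tracks) {
      for (i in seq_len(nrow(rows))) {
        tot <- tot + sum(tr$chrom == rows$chrom[i] & tr$strand == rows$strand[i] &
                           tr$position >= rows$start[i] & tr$position < rows$end[i])
      }
    }
    tot
  }
  rate_i <- count_in(intron) / (intron$end - intron$start)
  len_b <- sum(nonretained$end - nonretained$start)
  rate_b <- count_in(nonretained) / len_b
  if (rate_b == 0) return(NA_real_)
  rate_i / rate_b
}

#' Per-intron enrichment for all focal introns of a simulated genome
#'
#' @param tracks named list of `irtax_crosslinks`.
#' @param genome output of [simulate_genome_and_introns()].
#' @return named numeric vector over focal intron ids (`NA` where undefined).
#' @export
per_intron_enrichment_all <- function(tracks, genome) {
  ints <- genome$introns
  vapply(seq_len(nrow(genome$focal)), function(i) {
    id <- genome$focal$intron_id[i]
    gene <- genome$focal$gene_id[i]
    rows <- ints[ints$gene_id == gene, , drop = FALSE]
    per_intron_enrichment(tracks, rows[rows$intron_id == id, , drop = FALSE],
                          rows[rows$intron_id != id, , drop = FALSE])
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, genome$focal$intron_id)
}

#' RBPs significantly enriched in a group
#'
#' @param table enrichment data.frame from [enrichment_table()] or
#'   [group_enrichment()].
#' @param alpha p-value threshold (default 0.01, uncorrected as the analysis
#'   reports raw Fisher p-values).
#' @param adjust set `TRUE` to apply Benjamini-Hochberg within the table
#'   first.
#' @return named list: for each group, the RBPs with `p < alpha` and
#'   `enrichment > 1`.
#' @export
significant_rbps <- function(table, alpha = 0.01, adjust = FALSE) {
  p <- if (adjust) stats::p.adjust(table$p_value, "BH") else table$p_value
  sel <- !is.na(p) & p < alpha & !is.na(table$enrichment) & table$enrichment > 1
  lapply(split(table$rbp[sel], table$group[sel]), unique)
}

#' Hierarchical clustering of groups by enrichment profiles
#'
#' Groups are clustered on their concatenated per-region enrichment vectors
#' (RBPs x scopes) with Manhattan distance and Ward linkage. Undefined
#' scores are imputed as 1.0 (no enrichment) with a message. Groups are
#' ordered by label before clustering so the tree is input-order invariant.
#'
#' @param table enrichment data.frame.
#' @param scopes scopes to concatenate (default R1..R5).
#' @return an `hclust` object over the groups.
#' @export
cluster_groups <- function(table, scopes = c("R1", "R2", "R3", "R4", "R5")) {
  tab <- table[table$scope %in% scopes, ]
  groups <- sort(unique(tab$group))
  if (length(groups) < 2)
    stop_irtax("need >= 2 groups to cluster", "irtax_clustering_error")
  feats <- sort(unique(paste(tab$rbp, tab$scope, sep = ".")))
  m <- matrix(NA_real_, length(groups), length(feats),
              dimnames = list(groups, feats))
  m[cbind(match(tab$group, groups),
          match(paste(tab$rbp, tab$scope, sep = "."), feats))] <- tab$enrichment
  if (anyNA(m)) {
    message(sprintf("%d undefined enrichment scores imputed as 1.0", sum(is.na(m))))
    m[is.na(m)] <- 1
  }
  stats::hclust(stats::dist(m, method = "manhattan"), method = "ward.D2")
}
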