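# Genome layout used by the generator: genes are laid head-to-tail on a
# single synthetic chromosome, each with `introns_per_gene` introns separated
# by fixed-length exons. The first intron of each gene is the focal
# (retained) intron carrying the archetype label; the remaining introns are
# non-retained background used by the per-intron enrichment statistic.

#' Simulate a synthetic genome with annotated introns
#'
#' Generates random nucleotide sequence with controlled per-intron GC content
#' and length, and intron records whose flanking exons are always at least
#' 30 nt (so the five splice-site-anchored regions are well defined when the
#' intron is at least 91 nt). Gene strands alternate so both orientations are
#' exercised.
#'
#' @param config an [sim_config()]; uses `intron_length` (median), `exon_length`,
#'   `gc_target`, `introns_per_gene` (mean), `n_introns_per_group` and `seed`.
#'   Intron lengths are drawn log-normally around `intron_length` (floored at
#'   91 nt) and the intron count per gene varies around `introns_per_gene`,
#'   so length and intron-number features carry natural variation.
#' @return list with `sequences` (named character, one chromosome),
#'   `introns` (an `irtax_introns` table for all introns) and `focal`
#'   (data.frame `intron_id`, `gene_id`, `group` for the retained introns,
#'   ids matching [simulate_pir()]).
#' @export
simulate_genome_and_introns <- function(config) {
  if (config$intron_length < 91)
    stop_irtax("intron_length must be >= 91 for the five-region layout",
               "irtax_config_error")
  if (config$exon_length < 30)
    stop_irtax("exon_length must be >= 30 so flanking regions fit",
               "irtax_config_error")
  groups <- names(archetype_specs())
  n <- config$n_introns_per_group
  exl <- config$exon_length
  gap <- 50L
  n_genes <- length(groups) * n

  with_seed(child_seed(config$seed, 202), {
    gene_id <- sprintf("gene_%s_%04d", rep(groups, each = n), rep(seq_len(n), length(groups)))
    strand <- rep(c("+", "-"), length.out = n_genes)
    kmin <- max(2L, config$introns_per_gene - 1L)
    k_per_gene <- sample(kmin:(config$introns_per_gene + 1L), n_genes, replace = TRUE)
    recs <- vector("list", n_genes)
    offset <- gap
    for (i in seq_len(n_genes)) {
      k <- k_per_gene[i]
      inl <- pmax(91L, as.integer(round(stats::rlnorm(k, log(config$intron_length), 0.3))))
      s <- offset + exl + c(0L, cumsum(inl[-k] + exl))
      e <- s + inl
      ord <- if (strand[i] == "+") seq_len(k) else rev(seq_len(k))
      id <- ifelse(ord == 1L, sub("^gene_", "int_", gene_id[i]),
                   sprintf("%s_nr%d", sub("^gene_", "int_", gene_id[i]), ord - 1L))
      recs[[i]] <- data.frame(
        intron_id = id, gene_id = gene_id[i], chrom = "chrS",
        start = s, end = e, strand = strand[i],
        upstream_exon_start = s - exl, downstream_exon_end = e + exl,
        stringsAsFactors = FALSE)
      offset <- e[k] + exl + gap
    }
    recs <- do.call(rbind, recs)
    rownames(recs) <- NULL
    chrom_len <- offset

    # Background sequence at 0.5 GC, introns rewritten with the target GC.
    base <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    for (i in seq_len(nrow(recs))) {
      inl <- recs$end[i] - recs$start[i]
      gc <- stats::rbinom(inl, 1, config$gc_target)
      base[(recs$start[i] + 1L):recs$end[i]] <-
        ifelse(gc == 1, sample(c("G", "C"), inl, replace = TRUE),
               sample(c("A", "T"), inl, replace = TRUE))
    }
    introns <- intron_records(recs$intron_id, recs$gene_id, recs$chrom,
                              recs$start, recs$end, recs$strand,
                              recs$upstream_exon_start, recs$downstream_exon_end)
    focal <- data.frame(intron_id = sub("^gene_", "int_", gene_id),
                        gene_id = gene_id,
                        group = rep(groups, each = n), stringsAsFactors = FALSE)
    list(sequences = c(chrS = paste(base, collapse = "")),
         introns = introns, focal = focal)
  })
}

#' Simulate cross-link tracks with planted regional enrichments
#'
#' For every (RBP, focal intron, region) the region carries at least one
#' cross-link event with probability `p0`, raised to `min(1, fold * p0)` for
#' planted `(rbp, group, region)` pairs; an event is placed uniformly within
#' the hit region. Optionally a uniform per-nucleotide background rate
#' (`bg_rate`) scatters additional events over *all* introns (retained and
#' non-retained), which is what the per-intron enrichment statistic consumes.
#'
#' @param config an [sim_config()]; uses `n_rbps`, `p0`, `enriched_pairs`,
#'   `seed`.
#' @param genome output of [simulate_genome_and_introns()].
#' @param truth data.frame `intron_id`, `group` (from [simulate_pir()] or
#'   `genome$focal`).
#' @param bg_rate per-nucleotide background event rate over whole introns
#'   (default 0: regional hit fractions then sit exactly on the
#'   `min(1, fold * p0)` scale).
#' @return list with `tracks` (list of `irtax_crosslinks`) and `truth`
#'   (the planted `(rbp, group, region, fold)` table, possibly empty).
#' @export
simulate_crosslinks <- function(config, genome, truth, bg_rate = 0) {
  regions <- define_regions(genome$introns)
  focal_ids <- genome$focal$intron_id
  group_of <- stats::setNames(truth$group, truth$intron_id)
  pairs <- config$enriched_pairs
  if (!is.null(pairs)) {
    capped <- pmin(1, pairs$fold * config$p0)
    if (any(pairs$fold * config$p0 > 1))
      warning("fold * p0 exceeds 1 for some planted pairs; probability capped at 1")
  }
  rbps <- sprintf("RBP%02d", seq_len(config$n_rbps))
  reg_focal <- regions[regions$intron_id %in% focal_ids & regions$valid, ]

  with_seed(child_seed(config$seed, 303), {
    tracks <- lapply(rbps, function(rb) {
      p <- rep(config$p0, nrow(reg_focal))
      if (!is.null(pairs)) {
        for (r in seq_len(nrow(pairs))) {
          if (pairs$rbp[r] != rb) next
          sel <- reg_focal$region == pairs$region[r] &
            group_of[reg_focal$intron_id] == pairs$group[r]
          p[sel] <- min(1, pairs$fold[r] * config$p0)
        }
      }
      hit <- stats::runif(nrow(reg_focal)) < p
      pos <- reg_focal$start[hit] +
        floor(stats::runif(sum(hit)) * (reg_focal$end[hit] - reg_focal$start[hit]))
      chrom <- rep("chrS", sum(hit))
      strand <- reg_focal$strand[hit]
      if (bg_rate > 0) {
        ints <- genome$introns
        nbg <- stats::rpois(nrow(ints), bg_rate * (ints$end - ints$start))
        idx <- rep(seq_len(nrow(ints)), nbg)
        bgpos <- ints$start[idx] +
          floor(stats::runif(length(idx)) * (ints$end[idx] - ints$start[idx]))
        pos <- c(pos, bgpos)
        chrom <- c(chrom, ints$chrom[idx])
        strand <- c(strand, ints$strand[idx])
      }
      crosslink_track(rb, chrom, as.integer(pos), strand)
    })
    names(tracks) <- rbps
    list(tracks = tracks,
         truth = pairs %||% data.frame(rbp = character(), group = character(),
                                       region = character(), fold = numeric()))
  })
}
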