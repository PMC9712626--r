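#' Write a complete set of simulated pipeline inputs to disk
#'
#' Generates every input the pipeline consumes - PIR table, sample sheet,
#' intron annotation (extended BED), genome FASTA, per-RBP cross-link BEDs,
#' miRNA target sets (GMT), DE tables and a conservation bedGraph - together
#' with ground-truth tables, all derived from one master seed.
#'
#' @param config an [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible named character vector of the written file paths.
#' @export
simulate_inputs <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  seed <- config$seed

  sim <- simulate_pir(config)
  genome <- simulate_genome_and_introns(config)
  xl <- simulate_crosslinks(config, genome, sim$truth, bg_rate = 0.002)
  expr <- simulate_expression(config)

  write_sample_sheet(config$design, p("samples.tsv"), seed = seed)
  write_pir_table(sim$pir, p("pir.tsv"), seed = seed)
  write_intron_bed(genome$introns, p("introns.bed"), seed = seed)
  write_sequences(genome$sequences, p("genome.fa"))
  dir.create(p("crosslinks"), showWarnings = FALSE)
  for (rb in names(xl$tracks))
    write_crosslink_bed(xl$tracks[[rb]], p("crosslinks", paste0(rb, ".bed")),
                        seed = seed)
  write_gmt(expr$target_sets, p("target_sets.gmt"))
  write_de_table(expr$de, p("de.tsv"), seed = seed)
  # per-100nt conservation windows over the synthetic chromosome
  cons <- with_seed(child_seed(seed, 505), {
    len <- nchar(genome$sequences[["chrS"]])
    starts <- seq(0L, len - 1L, by = 100L)
    data.frame(chrom = "chrS", start = starts,
               end = pmin(starts + 100L, len),
               score = round(stats::runif(length(starts)), 3))
  })
  writeLines(c(sprintf("%s\t%d\t%d\t%.3f", cons$chrom, cons$start, cons$end,
                       cons$score)), p("conservation.bedGraph"))
  write_tsv_commented(sim$truth, p("truth_groups.tsv"), seed = seed)
  write_tsv_commented(expr$truth, p("truth_genes.tsv"), seed = seed)
  utils::write.table(data.frame(gene_id = rownames(expr$mat),
                                round(expr$mat, 6), check.names = FALSE),
                     p("expression_log2.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(samples = p("samples.tsv"), pir = p("pir.tsv"),
             introns = p("introns.bed"), genome = p("genome.fa"),
             gmt = p("target_sets.gmt"), de = p("de.tsv"),
             conservation = p("conservation.bedGraph"),
             truth_groups = p("truth_groups.tsv"),
             truth_genes = p("truth_genes.tsv"),
             expression = p("expression_log2.tsv"))
  invisible(files)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_irtax(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "irtax_stage_error")
  })
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes the stages in order - expression gate, retention filters and
#' classification, spatiotemporal taxonomy, cross-link enrichment, intron
#' features, miRNA activity - writing each stage's tables under `out_dir`
#' and returning a manifest with md5 checksums. Reruns with the same config
#' and seed are byte-identical.
#'
#' @param config an [sim_config()].
#' @param out_dir output directory.
#' @param alpha significance level used by the gate and enrichment reports.
#' @return list with `manifest` (data.frame `file`, `md5`) and the main
#'   in-memory results (`gate`, `ir_calls`, `taxonomy`, `enrichment`,
#'   `features`, `mirna`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("irtax_"),
                         alpha = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  seed <- config$seed

  sim <- run_stage("simulate", {
    list(pir = simulate_pir(config), genome = simulate_genome_and_introns(config),
         expr = simulate_expression(config))
  })
  xl <- run_stage("simulate", simulate_crosslinks(config, sim$genome,
                                                  sim$pir$truth, bg_rate = 0.002))

  gate <- run_stage("gate", call_expressed(sim$expr$mat, config$design,
                                           alpha = alpha, seed = seed))
  run_stage("gate", write_tsv_commented(
    data.frame(gene_id = rownames(gate$expressed), gate$expressed,
               check.names = FALSE), p("expressed.tsv"), seed = seed))

  pir <- sim$pir$pir
  kept <- run_stage("classify", prevalence_filter(pir))
  calls <- run_stage("classify", classify_nirt_cirt(pir))
  d14 <- config$vcp_effect_day
  deltas <- run_stage("classify", call_delta_pir(
    pir, sprintf("cytoplasm.div%d.control", d14),
    sprintf("cytoplasm.div%d.mutant", d14)))
  run_stage("classify", write_tsv_commented(calls, p("ir_calls.tsv"), seed = seed))
  run_stage("classify", write_tsv_commented(deltas, p("delta_pir.tsv"), seed = seed))

  tax <- run_stage("taxonomy", assign_taxonomy(
    pir_subset(pir, fraction = "nucleus"),
    pir_subset(pir, fraction = "cytoplasm"), seed = seed))
  run_stage("taxonomy", write_tsv_commented(tax, p("taxonomy.tsv"), seed = seed))

  regions <- run_stage("clip", define_regions(sim$genome$introns))
  hitm <- run_stage("clip", build_hit_matrix(xl$tracks, regions, sim$genome$introns))
  groups <- split(tax$intron_id, tax$group)
  groups <- groups[names(groups) != "unassigned"]
  enr <- run_stage("clip", enrichment_table(
    hitm, groups, background = sim$genome$focal$intron_id,
    scopes = c("R1", "R2", "R3", "R4", "R5", "intron")))
  run_stage("clip", write_tsv_commented(enr, p("enrichment.tsv"), seed = seed))

  pie <- run_stage("features", per_intron_enrichment_all(xl$tracks, sim$genome))
  feats <- run_stage("features", intron_feature_table(
    sim$genome$introns[match(sim$genome$focal$intron_id,
                             sim$genome$introns$intron_id), ],
    sim$genome$sequences, all_introns = sim$genome$introns,
    rbp_enrichment = pie))
  anova <- run_stage("features", pir_feature_anova(
    feats, max_pir(pir, "nucleus")[feats$intron_id],
    feature_cols = c("length_feature", "gc", "rbp_enrichment",
                     "n_introns_in_gene")))
  run_stage("features", write_tsv_commented(feats, p("features.tsv"), seed = seed))
  run_stage("features", write_tsv_commented(anova, p("feature_anova.tsv"), seed = seed))

  de_time <- sim$expr$de[sim$expr$de$contrast_label == "div7_to_div14.control", ]
  de_vcp <- sim$expr$de[sim$expr$de$contrast_label == "mutant_vs_control.div14", ]
  universe <- gate$universe
  mirna <- run_stage("mirna", {
    sets <- sim$expr$target_sets
    shift <- do.call(rbind, lapply(names(sets), function(s) {
      target_shift_test(de_vcp, sets[[s]], universe, set_name = s)
    }))
    conc <- do.call(rbind, lapply(names(sets), function(s) {
      target_concordance_test(de_time, de_vcp, sets[[s]], -1, 1, universe,
                              set_name = s)
    }))
    # mutant PIR shift of the recovered group best matching the perturbed
    # archetype (largest planted effect)
    truth_groups <- split(sim$pir$truth$intron_id, sim$pir$truth$group)
    perturbed <- names(which.max(config$vcp_effect))
    overlap <- vapply(groups, function(g)
      length(intersect(g, truth_groups[[perturbed]])), numeric(1))
    best <- names(which.max(overlap))
    shift_test <- group_pir_shift_test(pir, groups[[best]],
                                       fraction = "cytoplasm", div_day = d14)
    list(shift = shift, concordance = conc, pir_shift = shift_test,
         perturbed_group = best)
  })
  run_stage("mirna", write_tsv_commented(mirna$shift, p("mirna_shift.tsv"), seed = seed))
  run_stage("mirna", write_tsv_commented(mirna$concordance, p("mirna_concordance.tsv"),
                                         seed = seed))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv_commented(manifest, p("manifest.tsv"), seed = seed)
  list(manifest = manifest, gate = gate, prevalence = kept, ir_calls = calls,
       delta_pir = deltas, taxonomy = tax, enrichment = enr, features = feats,
       feature_anova = anova, mirna = mirna)
}
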