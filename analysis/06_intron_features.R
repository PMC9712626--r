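#!/usr/bin/env Rscript
# Per-intron sequence features (length, GC, conservation, per-intron
# cross-link enrichment over the gene's non-retained introns, introns per
# gene) and the nested-model ANOVA relating each feature to the maximum
# nuclear / cytoplasmic PIR.
source("analysis/00_common.R")

samples <- read_sample_sheet(file.path(SIMDIR, "samples.tsv"))
pir <- read_pir_table(file.path(SIMDIR, "pir.tsv"), samples)
introns <- read_intron_bed(file.path(SIMDIR, "introns.bed"))
seqs <- as.character(read_sequences(file.path(SIMDIR, "genome.fa")))
cons <- read_conservation_bedgraph(file.path(SIMDIR, "conservation.bedGraph"))
beds <- list.files(file.path(SIMDIR, "crosslinks"), full.names = TRUE)
tracks <- lapply(beds, function(b)
  read_crosslink_bed(b, sub("\\.bed$", "", basename(b))))

focal_ids <- introns$intron_id[!grepl("_nr", introns$intron_id)]
focal <- introns[match(focal_ids, introns$intron_id), ]
genome <- list(introns = introns, sequences = seqs,
               focal = data.frame(intron_id = focal_ids,
                                  gene_id = focal$gene_id))
pie <- per_intron_enrichment_all(tracks, genome)
feats <- intron_feature_table(focal, seqs, all_introns = introns,
                              conservation = cons, rbp_enrichment = pie)

out <- resdir("features")
write.table(feats, file.path(out, "features.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

for (frac in c("nucleus", "cytoplasm")) {
  resp <- max_pir(pir, frac)[feats$intron_id]
  av <- pir_feature_anova(feats, resp)
  write.table(av, file.path(out, sprintf("anova_%s.tsv", frac)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("ANOVA of max %s PIR on features:\n", frac))
  print(av, row.names = FALSE)
}
cat(sprintf("Feature table for %d focal introns (median length %d nt, mean GC %.2f)\n",
            nrow(feats), as.integer(median(feats$length_nt)), mean(feats$gc)))
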