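#!/usr/bin/env Rscript
# Generate the synthetic study: a nucleo-cytoplasmic PIR time course over
# six differentiation days (4 control + 3 mutant clones), a synthetic
# genome with annotated introns, per-RBP cross-link tracks, a bimodal
# expression matrix with differential-expression tables, and miRNA target
# sets - together with ground-truth labels for every planted structure.
source("analysis/00_common.R")

cfg <- sim_config(seed = SEED)
files <- simulate_inputs(cfg, SIMDIR)

samples <- read_sample_sheet(files[["samples"]])
pir <- read_pir_table(files[["pir"]], samples)
cat(sprintf("Simulated %d introns x %d samples (%d conditions)\n",
            nrow(pir$values), ncol(pir$values),
            length(unique(condition_of(samples)))))
cat(sprintf("Genome: %d introns across %d genes; %d RBP tracks; %d genes expressed-scale\n",
            nrow(read_intron_bed(files[["introns"]])),
            length(unique(read_intron_bed(files[["introns"]])$gene_id)),
            cfg$n_rbps, cfg$n_genes))
cat("Inputs written under", SIMDIR, "\n")
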