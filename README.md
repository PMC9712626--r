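# irtax — spatiotemporal taxonomy of retained introns

Intron retention (IR) is a major mode of alternative splicing in neuronal
differentiation: many transcripts keep one or more introns, and while most
such transcripts are detained in the nucleus, a substantial class reaches
the cytoplasm intact. `irtax` is an R package for dissecting this process
from nucleo-cytoplasmic fractionation RNA-seq time courses. It takes
percent-intron-retention (PIR) matrices (introns × samples, PIR ∈ [0, 100])
with a sample sheet (fraction × differentiation day × genotype × clone), and
provides:

* an **expression gate**: per-sample two-component Gaussian mixtures on
  log2 counts; a gene is reliably expressed in a condition iff
  P(non-expressed) < 1% in every sample of that condition;
* **retention filters**: prevalence (PIR > 10 in ≥ 3 samples of a
  compartment), nuclear vs cytoplasmic retained-transcript classification
  (NIRT: PIR_nuc > 20 & PIR_cyt < 5; CIRT: PIR_nuc > 20 & PIR_cyt > 15), and
  differential retention (|ΔPIR| ≥ 15 between conditions);
* the **SVD taxonomy**: per-compartment singular value decomposition of the
  (row-centered) PIR matrix; introns scored against each right singular
  vector v⃗ₖ by Pearson correlation and projection x⃗ᵢᵀv⃗ₖ; extremes selected
  by k-means on the standardized score pairs; assembly into nuclear (N*) and
  cytoplasmic (C*) dynamic groups;
* **CLIP enrichment**: five 30-nt splice-site-anchored regions (R1–R5),
  per-(intron, RBP, region) cross-link hit matrices, group-over-background
  enrichment with one-sided Fisher tests, and Manhattan/Ward clustering of
  groups by enrichment profiles;
* **intron features**: GC, length, median conservation, per-intron
  cross-link enrichment over the gene's non-retained introns, nested-model
  ANOVA of max PIR on the features, and a 50-nt-rule premature termination
  codon scan;
* **miRNA activity**: Welch shift tests of predicted-target log2FC,
  one-sided Fisher concordance across two contrasts, set-overlap tests, and
  a mixed-effects genotype test of group PIR
  (PIR ~ genotype + (1 | patient));
* a **synthetic-data generator** reproducing the assumed study design (six
  differentiation days × two fractions × 4+3 clones, nine PIR archetypes, a
  unidirectional mutant perturbation at day 14, planted cross-link
  enrichments and anticorrelated miRNA-target shifts) with ground-truth
  labels, so every stage has a parameter-recovery test.

The methods vignette (`vignettes/irtax-methods.Rmd`) documents the models,
parameters and design decisions in detail.

## Worked example

The `analysis/` scripts run the whole study on synthetic data
(`Rscript analysis/01_simulate.R --seed 1`, then `02`…`07` in order,
writing tables under `results/`). The core loop in code:

```r
library(irtax)

cfg <- sim_config(seed = 1)          # defaults = the assumed study design
sim <- simulate_pir(cfg)             # PIR matrix + true group labels
tax <- assign_taxonomy(pir_subset(sim$pir, fraction = "nucleus"),
                       pir_subset(sim$pir, fraction = "cytoplasm"), seed = 1)
truth <- setNames(sim$truth$group, sim$truth$intron_id)
assigned <- tax$group != "unassigned"
adjusted_rand_index(truth[tax$intron_id][assigned], tax$group[assigned])
#> [1] 0.8857443
mean(assigned)
#> [1] 0.78
```

The taxonomy recovers the seven *dynamic* archetypes essentially cleanly
(adjusted Rand index ≈ 0.89 over assigned introns at noise sd 5); the two
temporally flat archetypes carry no dynamic signal after row-centering and
are reported as unassigned, which is why coverage sits near 7/9.

Running `analysis/07_mirna_activity.R` after the earlier stages prints the
end-to-end anticorrelation motif on the same simulation:

```
Perturbed-archetype group recovered as 'C5'
Mutant cytoplasmic PIR shift at DIV 14: +14.5 PIR points (p = 2.76e-05, lmm)
    set_name t_statistic      p_value mean_target
 miR_planted   9.7479179 7.184636e-19  0.544391075
 miR_control  -0.5913534 5.549041e-01 -0.006659642
```

i.e. the group matching the perturbed archetype shows a significant mutant
PIR increase at day 14 while its linked miRNA target set shows a
significant expression up-shift in the mutant contrast — and the
negative-control target set shows neither.

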