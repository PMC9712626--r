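test_that("zero-noise PIR equals the archetype means exactly", {
  cfg <- fast_config(seed = 3, noise_sd = 0)
  sim <- simulate_pir(cfg)
  arch <- archetype_specs()
  ctrl <- pir_subset(sim$pir, genotype = "control")
  for (g in c("N2", "C5")) {
    ids <- sim$truth$intron_id[sim$truth$group == g]
    for (j in seq_len(nrow(ctrl$samples))) {
      prof <- if (ctrl$samples$fraction[j] == "nucleus")
        arch[[g]]$nuclear_profile else arch[[g]]$cytoplasmic_profile
      expect_equal(unname(ctrl$values[ids, j]),
                   rep(prof[[as.character(ctrl$samples$div_day[j])]], length(ids)))
    }
  }
})

test_that("the mutant perturbation is additive, cytoplasmic and at DIV 14 only", {
  cfg <- fast_config(seed = 3, noise_sd = 0)
  sim <- simulate_pir(cfg)
  arch <- archetype_specs()
  mut_cyt <- pir_subset(sim$pir, genotype = "mutant", fraction = "cytoplasm")
  ids <- sim$truth$intron_id[sim$truth$group == "C5"]
  for (d in c(7L, 14L)) {
    col <- which(mut_cyt$samples$div_day == d)[1]
    expected <- arch$C5$cytoplasmic_profile[[as.character(d)]] +
      if (d == 14L) cfg$vcp_effect[["C5"]] else 0
    expect_equal(unname(mut_cyt$values[ids, col]), rep(expected, length(ids)))
  }
})

test_that("the generator is deterministic in its seed", {
  cfg <- fast_config(seed = 11, noise_sd = 5)
  expect_identical(simulate_pir(cfg), simulate_pir(cfg))
  g1 <- simulate_genome_and_introns(cfg)
  expect_identical(g1, simulate_genome_and_introns(cfg))
  x1 <- simulate_crosslinks(cfg, g1, simulate_pir(cfg)$truth)
  expect_identical(x1, simulate_crosslinks(cfg, g1, simulate_pir(cfg)$truth))
  expect_identical(simulate_expression(cfg)$mat, simulate_expression(cfg)$mat)
})

test_that("noisy group means concentrate at the archetype means (CLT)", {
  cfg <- sim_config(seed = 9, n_introns_per_group = 200, noise_sd = 5,
                    n_rbps = 2, n_genes = 100, n_targets = 10)
  sim <- simulate_pir(cfg)
  arch <- archetype_specs()
  ctrl_nuc <- pir_subset(sim$pir, genotype = "control", fraction = "nucleus")
  n_rep <- length(unique(ctrl_nuc$samples$clone_id))
  for (g in c("N3", "C1", "C6")) {
    ids <- sim$truth$intron_id[sim$truth$group == g]
    for (d in attr(cfg$design, "design_days")) {
      cols <- ctrl_nuc$samples$div_day == d
      mu <- mean(ctrl_nuc$values[ids, cols])
      expect_lt(abs(mu - arch[[g]]$nuclear_profile[[as.character(d)]]),
                3 * 5 / sqrt(200 * n_rep))
    }
  }
})

test_that("simulated intron GC tracks the binomial expectation", {
  cfg <- fast_config(seed = 5, gc_target = 0.5)
  genome <- simulate_genome_and_introns(cfg)
  ids <- genome$focal$intron_id[1:50]
  for (id in ids) {
    r <- genome$introns[genome$introns$intron_id == id, ]
    s <- substr(genome$sequences[["chrS"]], r$start + 1, r$end)
    len <- r$end - r$start
    expect_lt(abs(gc_content(s) - 0.5), 3 * sqrt(0.25 / len) + 1e-9)
  }
})

test_that("minus-strand introns transcribe as the reverse complement", {
  cfg <- fast_config(seed = 5)
  genome <- simulate_genome_and_introns(cfg)
  r <- genome$introns[genome$introns$strand == "-", ][1, ]
  s <- substr(genome$sequences[["chrS"]], r$start + 1, r$end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc))), s)
  expect_equal(gc_content(rc), gc_content(s))  # GC strand-invariant
  # the focal (transcript-first) intron of a minus-strand gene is the
  # genomic-last intron of that gene
  gene <- genome$introns[genome$introns$gene_id == r$gene_id, ]
  focal <- gene$intron_id[!grepl("_nr", gene$intron_id)]
  expect_equal(gene$start[gene$intron_id == focal], max(gene$start))
})

test_that("every simulated intron keeps >= 30 nt flanking exons and >= 91 nt length", {
  genome <- simulate_genome_and_introns(fast_config(seed = 8))
  ints <- genome$introns
  expect_true(all(ints$start - ints$upstream_exon_start >= 30))
  expect_true(all(ints$downstream_exon_end - ints$end >= 30))
  expect_true(all(ints$end - ints$start >= 91))
})

test_that("cross-link hit fractions sit on the planted probability scale", {
  # baseline: all folds 1 -> fractions within binomial CI of p0
  cfg <- sim_config(seed = 13, n_introns_per_group = 100, n_rbps = 3, p0 = 0.2,
                    n_genes = 100, n_targets = 10)
  genome <- simulate_genome_and_introns(cfg)
  truth <- data.frame(intron_id = genome$focal$intron_id,
                      group = genome$focal$group)
  xl <- simulate_crosslinks(cfg, genome, truth)
  regions <- define_regions(genome$introns)
  hits <- build_hit_matrix(xl$tracks, regions, genome$introns)
  frac <- mean(hits$hits[genome$focal$intron_id, , "R2"], na.rm = TRUE)
  n <- sum(!is.na(hits$hits[genome$focal$intron_id, , "R2"]))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))

  # planted fold 3, p0 0.2, 500 introns in the group -> fraction near 0.6
  cfg2 <- sim_config(seed = 14, n_introns_per_group = 500, n_rbps = 1, p0 = 0.2,
                     n_genes = 100, n_targets = 10,
                     enriched_pairs = data.frame(rbp = "RBP01", group = "C5",
                                                 region = "R3", fold = 3))
  genome2 <- simulate_genome_and_introns(cfg2)
  truth2 <- data.frame(intron_id = genome2$focal$intron_id,
                       group = genome2$focal$group)
  xl2 <- simulate_crosslinks(cfg2, genome2, truth2)
  hits2 <- build_hit_matrix(xl2$tracks, define_regions(genome2$introns),
                            genome2$introns)
  c5 <- truth2$intron_id[truth2$group == "C5"]
  frac2 <- mean(hits2$hits[c5, 1, "R3"], na.rm = TRUE)
  expect_lt(abs(frac2 - 0.6), 3 * sqrt(0.6 * 0.4 / 500))
})

test_that("probability capping warns when fold * p0 exceeds 1", {
  cfg <- fast_config(seed = 2, p0 = 0.6,
                     enriched_pairs = data.frame(rbp = "RBP01", group = "C1",
                                                 region = "R2", fold = 3))
  genome <- simulate_genome_and_introns(cfg)
  truth <- data.frame(intron_id = genome$focal$intron_id, group = genome$focal$group)
  expect_warning(simulate_crosslinks(cfg, genome, truth), "capped")
})

test_that("expression simulation plants the bimodal structure and target shifts", {
  cfg <- fast_config(seed = 21, expr_sd = 0)
  expr <- simulate_expression(cfg)
  off <- expr$truth$gene_id[!expr$truth$on]
  expect_true(all(expr$mat[off, ] == cfg$mu_off))

  cfg2 <- sim_config(seed = 22, n_genes = 3000, n_targets = 200,
                     target_shift = 0.5, expr_sd = 1,
                     n_introns_per_group = 10, n_rbps = 1)
  expr2 <- simulate_expression(cfg2)
  de_t <- expr2$de[expr2$de$contrast_label == "div7_to_div14.control", ]
  fc <- de_t$log2fc[de_t$gene_id %in% expr2$target_sets$miR_planted]
  # per-gene log2FC has se sqrt(2/4) * expr_sd; mean over 200 targets
  se <- sqrt(2 / 4) * 1 / sqrt(200)
  expect_lt(abs(mean(fc) - (-0.5)), 3 * se)
  # control target set is unshifted
  fc0 <- de_t$log2fc[de_t$gene_id %in% expr2$target_sets$miR_control]
  expect_lt(abs(mean(fc0)), 3 * se)
})

test_that("row-wise Welch statistics agree with stats::t.test", {
  withr::with_seed(31, {
    a <- matrix(rnorm(50 * 4), 50)
    b <- matrix(rnorm(50 * 3, 1), 50)
  })
  w <- irtax:::welch_t_rows(a, b)
  for (i in c(1, 17, 50)) {
    tt <- t.test(b[i, ], a[i, ], var.equal = FALSE)
    expect_equal(w$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("every generated file parses back through the readers", {
  cfg <- fast_config(seed = 17)
  dir <- withr::local_tempdir()
  files <- simulate_inputs(cfg, dir)
  samples <- read_sample_sheet(files[["samples"]])
  expect_equal(nrow(samples), nrow(cfg$design))
  pir <- read_pir_table(files[["pir"]], samples)
  expect_equal(nrow(pir$values), 9 * cfg$n_introns_per_group)
  introns <- read_intron_bed(files[["introns"]])
  expect_gt(nrow(introns), 0)
  expect_gt(length(read_gmt(files[["gmt"]])), 0)
  expect_gt(nrow(read_de_table(files[["de"]])), 0)
  expect_s4_class(read_conservation_bedgraph(files[["conservation"]]), "GRanges")
  expect_equal(length(read_sequences(files[["genome"]])), 1)
  beds <- list.files(file.path(dir, "crosslinks"), full.names = TRUE)
  expect_gt(length(beds), 0)
  for (b in beds) expect_gt(nrow(read_crosslink_bed(b, "x")), 0)
})
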