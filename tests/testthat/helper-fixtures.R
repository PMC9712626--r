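# Shared fixtures built in code.

# Minimal two-condition design: `n_rep` clones per genotype, one DIV, both
# fractions optional.
tiny_design <- function(div_days = c(0L, 14L), fractions = c("nucleus", "cytoplasm"),
                        n_ctrl = 2L, n_mut = 0L) {
  clones <- c(sprintf("c%d", seq_len(n_ctrl)),
              if (n_mut > 0) sprintf("m%d", seq_len(n_mut)))
  geno <- c(rep("control", n_ctrl), rep("mutant", n_mut))
  grid <- expand.grid(fraction = fractions, div_day = div_days,
                      i = seq_along(clones), stringsAsFactors = FALSE)
  sample_sheet(
    sample_id = sprintf("%s_d%d_%s", clones[grid$i], grid$div_day,
                        substr(grid$fraction, 1, 3)),
    fraction = grid$fraction, div_day = grid$div_day,
    genotype = geno[grid$i], clone_id = clones[grid$i],
    patient_id = toupper(clones[grid$i]), design_days = div_days)
}

random_pir <- function(n_introns, samples, na_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_introns * nrow(samples), 0, 100), n_introns,
                dimnames = list(sprintf("i%03d", seq_len(n_introns)),
                                samples$sample_id))
    if (na_frac > 0) m[runif(length(m)) < na_frac] <- NA
    pir_matrix(m, samples)
  })
}

# The six-intron toy PIR table with hand-computed retention calls.
# Design: 3 nuclear + 3 cytoplasmic samples, one condition per fraction.
toy_pir <- function() {
  samples <- tiny_design(div_days = 0L, n_ctrl = 3L)
  vals <- rbind(
    hi_both   = c(30, 30, 30, 20, 20, 20),  # nuc mean 30, cyt mean 20 -> CIRT
    nuc_only  = c(30, 30, 30,  4,  4,  4),  # cyt mean 4 -> NIRT
    gap_zone  = c(30, 30, 30, 10, 10, 10),  # cyt mean 10 in (5,15) -> neither
    low_nuc   = c(15, 15, 15, 20, 20, 20),  # nuc mean 15 <= 20 -> neither
    prev_pass = c(12, 12, 12,  1,  1,  1),  # >10 in 3 nuclear samples
    prev_fail = c(12, 12,  8,  1,  1,  1))  # >10 in only 2 nuclear samples
  samples2 <- samples[c(which(samples$fraction == "nucleus"),
                        which(samples$fraction == "cytoplasm")), ]
  attr(samples2, "design_days") <- attr(samples, "design_days")
  class(samples2) <- class(samples)
  colnames(vals) <- samples2$sample_id
  pir_matrix(vals, samples2)
}

# small sim config for fast tests
fast_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_introns_per_group = 30, n_rbps = 4,
             n_genes = 800, n_targets = 50, ...)
}
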