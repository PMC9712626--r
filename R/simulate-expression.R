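# Row-wise Welch t statistics (unequal variances, Welch-Satterthwaite df).
# Used to derive per-gene differential-expression tables from simulated
# replicates; cross-checked against stats::t.test in the test suite.
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(log2fc = mb - ma, t = t, df = df, p_value = p)
}

#' Simulate a bimodal log2 expression matrix and DE tables
#'
#' Per sample, off genes draw from `N(mu_off, expr_sd)` and on genes from
#' `N(mu_on, expr_sd)` on the log2 scale, giving the bimodal log2-count
#' histogram the expression gate assumes. A planted miRNA-target set of
#' `n_targets` on-genes is shifted by `-target_shift` log2 units in control
#' samples at `vcp_effect_day`, so that targets are down-shifted over time in
#' controls (day 7 to day 14) and up-shifted in the mutant-vs-control
#' contrast at day 14 - the anticorrelation motif the miRNA-activity module
#' tests for. A disjoint same-size control target set receives no shift.
#'
#' Differential expression is computed from the simulated replicates (clones)
#' by two-sided Welch t-tests for two contrasts in the chosen fraction:
#' `div7_to_div14.control` (day 14 minus day 7, control clones) and
#' `mutant_vs_control.div14`.
#'
#' @param config an [sim_config()].
#' @param fraction fraction in which DE contrasts are computed.
#' @return list with `mat` (genes x samples log2 expression), `de`
#'   (DE table over both contrasts), `truth` (per-gene `on`, `target`,
#'   `control_target` flags) and `target_sets` (named list usable as GMT).
#' @export
simulate_expression <- function(config, fraction = "nucleus") {
  design <- config$design
  d14 <- config$vcp_effect_day
  with_seed(child_seed(config$seed, 404), {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    on <- stats::runif(config$n_genes) < config$frac_on
    on_genes <- genes[on]
    if (length(on_genes) < 2 * config$n_targets)
      stop_irtax("too few expressed genes for the planted target sets",
                 "irtax_config_error")
    targ <- sample(on_genes, config$n_targets)
    ctrl_targ <- sample(setdiff(on_genes, targ), config$n_targets)

    mu <- matrix(ifelse(on, config$mu_on, config$mu_off),
                 config$n_genes, nrow(design),
                 dimnames = list(genes, design$sample_id))
    shift_cols <- design$genotype == "control" & design$div_day == d14
    mu[genes %in% targ, shift_cols] <-
      mu[genes %in% targ, shift_cols] - config$target_shift
    mat <- mu
    if (config$expr_sd > 0)
      mat <- mat + matrix(stats::rnorm(length(mu), 0, config$expr_sd),
                          nrow(mu), ncol(mu))

    sel <- function(frac, geno, day) {
      design$sample_id[design$fraction == frac & design$genotype == geno &
                         design$div_day == day]
    }
    de_time <- welch_t_rows(mat[, sel(fraction, "control", 7L), drop = FALSE],
                            mat[, sel(fraction, "control", d14), drop = FALSE])
    de_vcp <- welch_t_rows(mat[, sel(fraction, "control", d14), drop = FALSE],
                           mat[, sel(fraction, "mutant", d14), drop = FALSE])
    de <- rbind(
      data.frame(gene_id = genes, log2fc = de_time$log2fc,
                 p_value = pmax(de_time$p_value, .Machine$double.xmin),
                 contrast_label = "div7_to_div14.control",
                 stringsAsFactors = FALSE),
      data.frame(gene_id = genes, log2fc = de_vcp$log2fc,
                 p_value = pmax(de_vcp$p_value, .Machine$double.xmin),
                 contrast_label = "mutant_vs_control.div14",
                 stringsAsFactors = FALSE))
    list(mat = mat, de = de,
         truth = data.frame(gene_id = genes, on = on,
                            target = genes %in% targ,
                            control_target = genes %in% ctrl_targ,
                            stringsAsFactors = FALSE),
         target_sets = list(miR_planted = targ, miR_control = ctrl_targ))
  })
}
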