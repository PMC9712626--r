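#' Welch t-test of target vs background expression changes
#'
#' Two-sided Welch (unequal variance) t-test comparing the log2 fold-changes
#' of a miRNA's predicted target genes against all other genes of the
#' universe, for one contrast.
#'
#' @param de DE table (`gene_id`, `log2fc`, `p_value`, `contrast_label`);
#'   must contain a single contrast or be pre-filtered.
#' @param targets character vector of predicted target gene ids.
#' @param universe character vector of analysis genes.
#' @param set_name label for the target set.
#' @return data.frame row: `set_name`, `t_statistic`, `df`, `p_value`,
#'   `mean_target`, `mean_background`, `n_target`, `n_background`.
#' @export
target_shift_test <- function(de, targets, universe, set_name = "targets") {
  if (length(unique(de$contrast_label)) > 1)
    stop_irtax("DE table contains several contrasts; filter to one",
               "irtax_data_error")
  de <- de[de$gene_id %in% universe & is.finite(de$log2fc), ]
  x_t <- de$log2fc[de$gene_id %in% targets]
  x_b <- de$log2fc[!de$gene_id %in% targets]
  if (length(x_t) < 5 || length(x_b) < 5)
    stop_irtax("need >= 5 target and >= 5 background genes with finite log2FC",
               "irtax_insufficient_data")
  if (stats::sd(x_t) == 0 && stats::sd(x_b) == 0 && mean(x_t) == mean(x_b)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
  } else {
    tt <- stats::t.test(x_t, x_b, var.equal = FALSE)
  }
  data.frame(set_name = set_name, t_statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             mean_target = mean(x_t), mean_background = mean(x_b),
             n_target = length(x_t), n_background = length(x_b),
             stringsAsFactors = FALSE)
}

#' Cross-contrast concordance test for a target set
#'
#' A gene is *concordant* when the sign of its log2FC in contrast A matches
#' `predicate_a` and the sign in contrast B matches `predicate_b` (strict
#' inequalities; zero fold-changes are never concordant). The one-sided
#' (greater) Fisher's exact test asks whether predicted targets are
#' over-represented among concordant genes relative to the rest of the
#' universe.
#'
#' @param de_a,de_b single-contrast DE tables sharing the gene universe.
#' @param targets predicted target gene ids.
#' @param predicate_a,predicate_b `-1` or `+1`: required sign of log2FC in
#'   each contrast.
#' @param universe analysis gene ids (present in both contrasts).
#' @param set_name label.
#' @return data.frame row: `set_name`, the 2x2 counts
#'   (`target_concordant`, `target_other`, `background_concordant`,
#'   `background_other`), `odds_ratio` (sample OR), `p_value`.
#' @export
target_concordance_test <- function(de_a, de_b, targets, predicate_a = -1,
                                    predicate_b = 1, universe,
                                    set_name = "targets") {
  fa <- stats::setNames(de_a$log2fc, de_a$gene_id)
  fb <- stats::setNames(de_b$log2fc, de_b$gene_id)
  genes <- intersect(universe, intersect(names(fa), names(fb)))
  genes <- genes[is.finite(fa[genes]) & is.finite(fb[genes])]
  if (length(genes) == 0)
    stop_irtax("empty universe intersection across contrasts", "irtax_data_error")
  conc <- (sign(fa[genes]) == predicate_a) & (sign(fb[genes]) == predicate_b)
  is_t <- genes %in% targets
  tab <- matrix(c(sum(is_t & conc), sum(is_t & !conc),
                  sum(!is_t & conc), sum(!is_t & !conc)), 2, 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "greater")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  data.frame(set_name = set_name,
             target_concordant = tab[1, 1], target_other = tab[1, 2],
             background_concordant = tab[2, 1], background_other = tab[2, 2],
             odds_ratio = or, p_value = ft$p.value, stringsAsFactors = FALSE)
}

#' Fisher overlap test between two gene sets
#'
#' Hypergeometric (one-sided, greater) probability of the observed overlap
#' given the two set sizes and the universe size. Symmetric in its two set
#' arguments.
#'
#' @param set_a,set_b gene id vectors, both subsets of `universe`.
#' @param universe analysis gene ids.
#' @return data.frame: `overlap`, `n_a`, `n_b`, `n_universe`, `p_value`.
#' @export
significant_overlap_test <- function(set_a, set_b, universe) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_irtax("sets must be contained in the universe", "irtax_data_error")
  set_a <- unique(set_a); set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  tab <- matrix(c(k, length(set_a) - k,
                  length(set_b) - k,
                  length(universe) - length(set_a) - length(set_b) + k),
                2, 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  data.frame(overlap = k, n_a = length(set_a), n_b = length(set_b),
             n_universe = length(universe), p_value = p)
}

#' Mixed-effects test of a genotype PIR shift in an intron group
#'
#' Models the PIR of the group's introns as `PIR ~ genotype + (1 | patient)`
#' by REML, so idiosyncratic patient variation is absorbed by the random
#' intercept; the reported effect is the genotype coefficient (mutant minus
#' control, PIR points) with a Satterthwaite p-value. When the random-effect
#' fit is degenerate the test falls back to a Welch t-test on per-patient
#' mean PIR, and the fallback is recorded.
#'
#' @param pir an `irtax_pir`.
#' @param group character vector of intron ids.
#' @param fraction compartment to test (default cytoplasm).
#' @param div_day optional DIV restriction (e.g. the perturbation day).
#' @return data.frame: `effect` (PIR points), `se`, `p_value`, `n_introns`,
#'   `n_patients`, `method` (`"lmm"` or `"welch_patient_means"`).
#' @export
group_pir_shift_test <- function(pir, group, fraction = "cytoplasm",
                                 div_day = NULL) {
  sub <- pir_subset(pir, fraction = fraction, div_day = div_day,
                    introns = intersect(group, rownames(pir$values)))
  if (length(unique(sub$samples$genotype)) < 2)
    stop_irtax("both genotypes required", "irtax_design_error")
  pat_geno <- unique(sub$samples[, c("patient_id", "genotype")])
  if (any(table(pat_geno$genotype) < 2))
    stop_irtax("need >= 2 patients per genotype", "irtax_design_error")
  long <- data.frame(
    pir = as.vector(sub$values),
    genotype = factor(rep(sub$samples$genotype, each = nrow(sub$values)),
                      levels = c("control", "mutant")),
    patient = rep(sub$samples$patient_id, each = nrow(sub$values)))
  long <- long[is.finite(long$pir), ]

  fit <- tryCatch({
    m <- suppressMessages(suppressWarnings(
      lmerTest::lmer(pir ~ genotype + (1 | patient), data = long, REML = TRUE)))
    co <- stats::coef(summary(m))["genotypemutant", ]
    if (!is.finite(co[["Pr(>|t|)"]])) stop("degenerate p")
    data.frame(effect = co[["Estimate"]], se = co[["Std. Error"]],
               p_value = co[["Pr(>|t|)"]], method = "lmm",
               stringsAsFactors = FALSE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    message("random-effect fit degenerate; falling back to Welch on patient means")
    pm <- stats::aggregate(pir ~ patient, long, mean)
    pm$genotype <- pat_geno$genotype[match(pm$patient, pat_geno$patient_id)]
    tt <- stats::t.test(pir ~ genotype, pm, var.equal = FALSE)
    fit <- data.frame(effect = diff(rev(tt$estimate))[[1]] * -1,
                      se = NA_real_, p_value = tt$p.value,
                      method = "welch_patient_means", stringsAsFactors = FALSE)
  }
  fit$n_introns <- nrow(sub$values)
  fit$n_patients <- nrow(pat_geno)
  fit
}
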