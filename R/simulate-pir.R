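#' The nine retained-intron archetypes
#'
#' Mean PIR anchor values per differentiation day and compartment for the nine
#' spatiotemporal dynamics the taxonomy targets: three nuclear-detained
#' programs (N1 stable nuclear / low cytoplasmic; N2 steady nuclear decline;
#' N3 transient nuclear peak) and six cytoplasmic programs (C1 steady decline
#' in both compartments; C2 steady rise in both; C3 terminal-stage cytoplasmic
#' rise; C4 consistently high in both; C5 early transient peak; C6 late
#' transient peak). Anchors are piecewise-linear through the design days and
#' are config-visible so tests can tighten or relax them. N-group cytoplasmic
#' means stay below 10 PIR; every C-group cytoplasmic profile reaches at least
#' 15 PIR at its peak.
#'
#' @param div_days the design days the anchors are defined over (length 6).
#' @return a list with one element per group, each holding `nuclear_profile`
#'   and `cytoplasmic_profile` (named numeric vectors over `div_days`) and
#'   `mutant_delta` (additive PIR shift per (compartment, day), zero unless
#'   set by [sim_config()]).
#' @export
archetype_specs <- function(div_days = c(0L, 3L, 7L, 14L, 21L, 35L)) {
  stopifnot(length(div_days) == 6)
  anchors <- list(
    N1 = list(nuc = c(25, 25, 25, 25, 25, 25), cyt = c(3, 3, 3, 3, 3, 3)),
    N2 = list(nuc = c(40, 33, 26, 19, 12, 5),  cyt = c(3, 3, 3, 3, 3, 3)),
    N3 = list(nuc = c(20, 30, 45, 30, 20, 15), cyt = c(4, 4, 4, 4, 4, 4)),
    C1 = list(nuc = c(45, 38, 31, 24, 17, 10), cyt = c(40, 33, 26, 19, 12, 5)),
    C2 = list(nuc = c(10, 17, 24, 31, 38, 45), cyt = c(5, 12, 19, 26, 33, 40)),
    C3 = list(nuc = c(20, 20, 20, 20, 21, 24), cyt = c(5, 5, 5, 5, 6, 45)),
    C4 = list(nuc = c(40, 40, 40, 40, 40, 40), cyt = c(30, 30, 30, 30, 30, 30)),
    C5 = list(nuc = c(20, 30, 45, 25, 20, 18), cyt = c(10, 20, 35, 15, 10, 8)),
    C6 = list(nuc = c(18, 18, 20, 26, 45, 22), cyt = c(8, 8, 8, 16, 35, 12)))
  lapply(anchors, function(a) {
    zero <- matrix(0, 2, 6, dimnames = list(c("nucleus", "cytoplasm"),
                                            as.character(div_days)))
    list(nuclear_profile = stats::setNames(a$nuc, div_days),
         cytoplasmic_profile = stats::setNames(a$cyt, div_days),
         mutant_delta = zero)
  })
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults encode the
#' study conditions the pipeline assumes: the [default_design()] sample sheet,
#' nine archetypes with 200 introns each, Gaussian PIR noise of 5 points, and
#' a unidirectional mutant perturbation applied at DIV 14 in the cytoplasm
#' (+15 PIR on C5, +5 on C1 and C3).
#'
#' @param n_introns_per_group introns simulated per archetype.
#' @param noise_sd Gaussian PIR noise, in PIR points.
#' @param seed master seed; all generator randomness derives from it.
#' @param design an `irtax_samples` sheet.
#' @param vcp_effect named numeric: additive cytoplasmic PIR shift per group
#'   at `vcp_effect_day` in mutant samples (must be >= 0, the perturbation is
#'   unidirectional).
#' @param vcp_effect_day DIV at which the mutant shift applies.
#' @param patient_sd sd (PIR points) of an optional per-patient random
#'   intercept shared by all introns of a patient's samples; default 0, in
#'   which case PIR is exactly archetype mean + mutant delta + noise.
#' @param n_rbps number of simulated RBP cross-link tracks.
#' @param p0 baseline probability that a 30-nt region carries >= 1 cross-link
#'   event.
#' @param enriched_pairs data.frame with columns `rbp`, `group`, `region`,
#'   `fold` giving planted regional enrichments (fold >= 1).
#' @param n_genes,frac_on,mu_off,mu_on,expr_sd log2 expression model: a gene
#'   is "on" with probability `frac_on`; on genes ~ N(mu_on, expr_sd), off
#'   genes ~ N(mu_off, expr_sd) per sample.
#' @param n_targets,target_shift miRNA-activity plant: `n_targets` target
#'   genes are shifted by `-target_shift` log2 units in control samples at the
#'   perturbation day (producing a down-shift over time in controls and an
#'   up-shift in the mutant-vs-control contrast at that day).
#' @param intron_length,exon_length,gc_target genome layout for
#'   [simulate_genome_and_introns()].
#' @param introns_per_gene introns per simulated gene (one retained, the rest
#'   non-retained background for per-intron enrichment).
#' @return a list of class `irtax_config`.
#' @export
sim_config <- function(n_introns_per_group = 200, noise_sd = 5, seed = 1L,
                       design = default_design(),
                       vcp_effect = c(C5 = 15, C1 = 5, C3 = 5),
                       vcp_effect_day = 14L, patient_sd = 0,
                       n_rbps = 12, p0 = 0.2, enriched_pairs = NULL,
                       n_genes = 4000, frac_on = 0.6, mu_off = 1, mu_on = 9,
                       expr_sd = 1, n_targets = 200, target_shift = 0.5,
                       intron_length = 300L, exon_length = 100L,
                       gc_target = 0.45, introns_per_gene = 3L) {
  if (n_introns_per_group < 1 || n_rbps < 1 || n_genes < 1)
    stop_irtax("counts must be positive", "irtax_config_error")
  if (noise_sd < 0 || patient_sd < 0)
    stop_irtax("noise_sd and patient_sd must be >= 0", "irtax_config_error")
  if (any(vcp_effect < 0))
    stop_irtax("mutant PIR shifts must be >= 0 (unidirectional)", "irtax_config_error")
  if (!is.null(enriched_pairs) && any(enriched_pairs$fold < 1))
    stop_irtax("planted folds must be >= 1", "irtax_config_error")
  if (mu_on <= mu_off)
    stop_irtax("mu_on must exceed mu_off", "irtax_config_error")
  if (!all(c("nucleus", "cytoplasm") %in% design$fraction))
    stop_irtax("design must include both fractions", "irtax_config_error")
  structure(as.list(environment()), class = "irtax_config")
}

#' Simulate a PIR matrix with ground-truth group labels
#'
#' Each intron is drawn from one of the nine archetypes; its PIR in sample
#' `s` is `clip(archetype mean(fraction, div) + mutant_delta * [genotype ==
#' mutant] + patient intercept + N(0, noise_sd), 0, 100)`. The mutant delta is
#' the configured cytoplasmic shift at `vcp_effect_day` only. Fully
#' reproducible from `config$seed`.
#'
#' @param config an [sim_config()].
#' @return list with `pir` (an `irtax_pir` over both fractions) and `truth`
#'   (data.frame `intron_id`, `group`).
#' @export
simulate_pir <- function(config) {
  design <- config$design
  days <- attr(design, "design_days")
  if (length(days) != 6)
    stop_irtax("archetypes are defined over a six-day design", "irtax_config_error")
  arch <- archetype_specs(days)
  for (g in names(config$vcp_effect)) {
    if (!g %in% names(arch))
      stop_irtax(sprintf("unknown group '%s' in vcp_effect", g), "irtax_config_error")
    arch[[g]]$mutant_delta["cytoplasm", as.character(config$vcp_effect_day)] <-
      config$vcp_effect[[g]]
  }
  groups <- names(arch)
  n <- config$n_introns_per_group
  intron_ids <- sprintf("int_%s_%04d", rep(groups, each = n), rep(seq_len(n), length(groups)))
  truth <- data.frame(intron_id = intron_ids, group = rep(groups, each = n),
                      stringsAsFactors = FALSE)

  with_seed(child_seed(config$seed, 101), {
    patients <- unique(design$patient_id)
    pat_eff <- stats::setNames(stats::rnorm(length(patients), 0, config$patient_sd),
                               patients)
    means <- matrix(NA_real_, length(intron_ids), nrow(design),
                    dimnames = list(intron_ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      fr <- design$fraction[j]
      d <- as.character(design$div_day[j])
      mut <- design$genotype[j] == "mutant"
      base <- vapply(groups, function(g) {
        prof <- if (fr == "nucleus") arch[[g]]$nuclear_profile else arch[[g]]$cytoplasmic_profile
        prof[[d]] + if (mut) arch[[g]]$mutant_delta[fr, d] else 0
      }, numeric(1))
      means[, j] <- rep(base, each = n) + pat_eff[[design$patient_id[j]]]
    }
    vals <- means
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(means), 0, config$noise_sd),
                            nrow(means), ncol(means))
    vals <- clip_pir(vals)
    list(pir = pir_matrix(vals, design), truth = truth,
         archetypes = arch)
  })
}
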