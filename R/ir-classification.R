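#' Prevalence filter: introns retained in enough samples of a compartment
#'
#' Keeps introns whose PIR strictly exceeds `min_pir` in at least
#' `min_samples` samples of the chosen compartment. Missing values never
#' count as passing.
#'
#' @param pir an `irtax_pir` object.
#' @param min_pir PIR threshold in percent (strict `>`), default 10.
#' @param min_samples minimum number of qualifying samples, default 3.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @return character vector of intron ids passing the filter.
#' @export
prevalence_filter <- function(pir, min_pir = 10, min_samples = 3,
                              compartment = "nucleus") {
  cols <- pir$samples$fraction == compartment
  if (!any(cols))
    stop_irtax(sprintf("compartment '%s' absent from sample sheet", compartment),
               "irtax_design_error")
  if (min_samples > sum(cols))
    stop_irtax("min_samples exceeds available samples in compartment",
               "irtax_config_error")
  sub <- pir$values[, cols, drop = FALSE]
  n_pass <- rowSums(!is.na(sub) & sub > min_pir)
  rownames(pir$values)[n_pass >= min_samples]
}

#' Classify introns as nuclear-only (NIRT) or nucleo-cytoplasmic (CIRT)
#'
#' With `S` the per-condition mean PIR (default) or the per-sample value
#' (`summarize = "any_sample"`): an intron is a CIRT when its maximal nuclear
#' `S` exceeds `nuc_min` *and* its maximal cytoplasmic `S` exceeds
#' `cyt_high`; an NIRT when the nuclear maximum exceeds `nuc_min` and the
#' cytoplasmic maximum stays below `cyt_low`; otherwise neither (the band
#' between `cyt_low` and `cyt_high` is a deliberate gap zone). All
#' inequalities are strict. Introns with an all-missing compartment are
#' classified `neither` and flagged.
#'
#' @param pir an `irtax_pir` with both compartments.
#' @param summarize `"condition_mean"` (default) or `"any_sample"`.
#' @param nuc_min,cyt_high,cyt_low thresholds in PIR percent (20 / 15 / 5).
#' @return data.frame with `intron_id`, `class` (`NIRT`/`CIRT`/`neither`),
#'   `max_pir_nucleus`, `max_pir_cytoplasm`, `condition_of_max` (condition or
#'   sample attaining the nuclear maximum) and `missing_compartment` flag.
#' @export
classify_nirt_cirt <- function(pir, summarize = c("condition_mean", "any_sample"),
                               nuc_min = 20, cyt_high = 15, cyt_low = 5) {
  summarize <- match.arg(summarize)
  if (!all(c("nucleus", "cytoplasm") %in% pir$samples$fraction))
    stop_irtax("both compartments required", "irtax_design_error")
  summarize_one <- function(frac) {
    sub <- pir_subset(pir, fraction = frac)
    if (summarize == "condition_mean") {
      s <- condition_means(sub)
    } else {
      s <- sub$values
    }
    all_na <- rowSums(!is.na(s)) == 0
    mx <- suppressWarnings(apply(s, 1, max, na.rm = TRUE))
    mx[all_na] <- NA_real_
    at <- colnames(s)[max.col(replace(s, is.na(s), -Inf), ties.method = "first")]
    at[all_na] <- NA_character_
    list(max = mx, at = at, all_na = all_na)
  }
  nuc <- summarize_one("nucleus")
  cyt <- summarize_one("cytoplasm")
  missing_comp <- nuc$all_na | cyt$all_na
  cls <- rep("neither", nrow(pir$values))
  ok <- !missing_comp
  cls[ok & nuc$max > nuc_min & cyt$max > cyt_high] <- "CIRT"
  cls[ok & nuc$max > nuc_min & cyt$max < cyt_low] <- "NIRT"
  data.frame(intron_id = rownames(pir$values), class = cls,
             max_pir_nucleus = nuc$max, max_pir_cytoplasm = cyt$max,
             condition_of_max = nuc$at, missing_compartment = missing_comp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differential-retention events between two conditions
#'
#' An event is reported when the absolute difference of mean PIR between the
#' two conditions reaches `min_delta` PIR points and (optionally) the host
#' gene is reliably expressed. `mean_delta` is condition `b` minus condition
#' `a`; `direction` is `"included"` for positive deltas (more retention in
#' `b`) and `"skipped"` otherwise.
#'
#' @param pir an `irtax_pir` object.
#' @param condition_a,condition_b condition labels as produced by
#'   [condition_of()].
#' @param min_delta minimum `|mean_delta|`, default 15 PIR points.
#' @param require_expressed optional character vector of expressed gene ids;
#'   requires `gene_map`.
#' @param gene_map optional named character vector intron_id -> gene_id.
#' @return data.frame `intron_id`, `contrast`, `mean_delta`, `direction`,
#'   `n_a`, `n_b` (effective non-missing sample counts).
#' @export
call_delta_pir <- function(pir, condition_a, condition_b, min_delta = 15,
                           require_expressed = NULL, gene_map = NULL) {
  cond <- condition_of(pir$samples)
  if (!condition_a %in% cond || !condition_b %in% cond)
    stop_irtax("contrast condition absent from sample sheet", "irtax_config_error")
  a <- pir$values[, cond == condition_a, drop = FALSE]
  b <- pir$values[, cond == condition_b, drop = FALSE]
  n_a <- rowSums(!is.na(a)); n_b <- rowSums(!is.na(b))
  delta <- rowMeans(b, na.rm = TRUE) - rowMeans(a, na.rm = TRUE)
  keep <- n_a > 0 & n_b > 0 & abs(delta) >= min_delta
  if (!is.null(require_expressed)) {
    if (is.null(gene_map))
      stop_irtax("require_expressed needs a gene_map", "irtax_config_error")
    keep <- keep & gene_map[rownames(pir$values)] %in% require_expressed
  }
  keep <- which(keep)  # drops NA comparisons (all-missing conditions)
  data.frame(intron_id = rownames(pir$values)[keep],
             contrast = rep(sprintf("%s -> %s", condition_a, condition_b),
                            length(keep)),
             mean_delta = delta[keep],
             direction = ifelse(delta[keep] > 0, "included", "skipped"),
             n_a = n_a[keep], n_b = n_b[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
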