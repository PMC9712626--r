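#' Sample sheet for a fractionated differentiation time course
#'
#' A sample sheet records, for every RNA-seq library, the subcellular fraction
#' it came from, the differentiation day (DIV, days in vitro), the genotype
#' (control or mutant) and the clone/patient of origin. All downstream
#' condition logic (a *condition* is a `(fraction, div_day, genotype)` triple)
#' is driven by this table.
#'
#' @param sample_id character, unique library identifiers.
#' @param fraction character, `"nucleus"` or `"cytoplasm"`.
#' @param div_day integer days in vitro, non-negative.
#' @param genotype character, `"control"` or `"mutant"`.
#' @param clone_id character clone labels.
#' @param patient_id character patient-of-origin labels.
#' @param design_days integer vector of admissible DIV values; defaults to the
#'   observed set.
#' @return a `data.frame` of class `irtax_samples`.
#' @export
sample_sheet <- function(sample_id, fraction, div_day, genotype, clone_id,
                         patient_id, design_days = NULL) {
  df <- data.frame(sample_id = as.character(sample_id),
                   fraction = as.character(fraction),
                   div_day = as.integer(div_day),
                   genotype = as.character(genotype),
                   clone_id = as.character(clone_id),
                   patient_id = as.character(patient_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop_irtax("duplicate sample_id in sample sheet", "irtax_schema_error")
  if (!all(df$fraction %in% c("nucleus", "cytoplasm")))
    stop_irtax("fraction must be 'nucleus' or 'cytoplasm'", "irtax_schema_error")
  if (!all(df$genotype %in% c("control", "mutant")))
    stop_irtax("genotype must be 'control' or 'mutant'", "irtax_schema_error")
  if (any(df$div_day < 0))
    stop_irtax("div_day must be >= 0", "irtax_schema_error")
  design_days <- sort(unique(as.integer(design_days %||% df$div_day)))
  if (!all(df$div_day %in% design_days))
    stop_irtax("div_day outside the declared design set", "irtax_schema_error")
  attr(df, "design_days") <- design_days
  class(df) <- c("irtax_samples", "data.frame")
  df
}

#' Default sample design: six DIV stages, two fractions, 4+3 clones
#'
#' Mirrors a nucleo-cytoplasmic fractionation time course across six
#' differentiation stages (DIV 0, 3, 7, 14, 21, 35) with four control clones
#' from four patients and three mutant clones from two patients, both
#' fractions sampled at every stage.
#'
#' @param div_days integer vector of sampling days.
#' @return an `irtax_samples` sample sheet (84 samples by default).
#' @export
default_design <- function(div_days = c(0L, 3L, 7L, 14L, 21L, 35L)) {
  clones <- data.frame(
    clone_id = c("ctrl1", "ctrl2", "ctrl3", "ctrl4", "mut1", "mut2", "mut3"),
    patient_id = c("P1", "P2", "P3", "P4", "P5", "P5", "P6"),
    genotype = c(rep("control", 4), rep("mutant", 3)),
    stringsAsFactors = FALSE)
  grid <- expand.grid(fraction = c("nucleus", "cytoplasm"),
                      div_day = as.integer(div_days),
                      idx = seq_len(nrow(clones)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cl <- clones[grid$idx, ]
  sample_sheet(
    sample_id = sprintf("%s_d%02d_%s", cl$clone_id, grid$div_day,
                        ifelse(grid$fraction == "nucleus", "nuc", "cyt")),
    fraction = grid$fraction, div_day = grid$div_day,
    genotype = cl$genotype, clone_id = cl$clone_id,
    patient_id = cl$patient_id, design_days = div_days)
}

#' Condition label for each sample
#'
#' @param samples an `irtax_samples` sheet.
#' @return character vector `"<fraction>.div<D>.<genotype>"` per sample.
#' @export
condition_of <- function(samples) {
  sprintf("%s.div%d.%s", samples$fraction, samples$div_day, samples$genotype)
}

#' Read / write a sample sheet as TSV
#'
#' @param path file path.
#' @param seed optional seed recorded in the output header.
#' @return `read_sample_sheet` returns an `irtax_samples` sheet;
#'   `write_sample_sheet` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("sample_id", "fraction", "div_day", "genotype", "clone_id", "patient_id")
  if (!all(need %in% names(df)))
    stop_irtax(paste("sample sheet missing columns:",
                     paste(setdiff(need, names(df)), collapse = ", ")),
               "irtax_schema_error")
  sample_sheet(df$sample_id, df$fraction, df$div_day, df$genotype,
               df$clone_id, df$patient_id)
}

#' @rdname read_sample_sheet
#' @param samples an `irtax_samples` sheet to write.
#' @export
write_sample_sheet <- function(samples, path, seed = NULL) {
  write_tsv_commented(as.data.frame(samples), path, seed = seed)
}
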