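#' Percent-intron-retention (PIR) matrix with attached sample metadata
#'
#' The central container of the pipeline: an introns-by-samples matrix of PIR
#' values in `[0, 100]` (missing values allowed, never imputed at this layer)
#' whose columns are described by an [sample_sheet()].
#'
#' @param values numeric matrix, introns in rows, samples in columns; row and
#'   column names required.
#' @param samples an `irtax_samples` sheet whose `sample_id`s match
#'   `colnames(values)` exactly (same order).
#' @return an object of class `irtax_pir` (list with `values`, `samples`).
#' @export
pir_matrix <- function(values, samples) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop_irtax("values must be a matrix with intron rownames and sample colnames",
               "irtax_schema_error")
  if (anyDuplicated(rownames(values)))
    stop_irtax("duplicate intron ids", "irtax_schema_error")
  if (!identical(colnames(values), samples$sample_id))
    stop_irtax("column ids do not match sample sheet sample_ids",
               "irtax_schema_error")
  bad <- which(!is.na(values) & (values < 0 | values > 100), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_irtax(sprintf("PIR value outside [0,100] at intron '%s', sample '%s' (%.6g)",
                       rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                       values[bad[1, , drop = FALSE]]),
               "irtax_range_error")
  }
  structure(list(values = values, samples = samples), class = "irtax_pir")
}

#' @export
print.irtax_pir <- function(x, ...) {
  cat(sprintf("PIR matrix: %d introns x %d samples (%d conditions, %.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              length(unique(condition_of(x$samples))),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.irtax_pir <- function(x) dim(x$values)

#' Subset a PIR matrix by samples and/or introns
#'
#' @param pir an `irtax_pir` object.
#' @param fraction,genotype,div_day optional sample filters.
#' @param introns optional character vector of intron ids to keep.
#' @return a new `irtax_pir` restricted to the matching samples/introns.
#' @export
pir_subset <- function(pir, fraction = NULL, genotype = NULL, div_day = NULL,
                       introns = NULL) {
  keep <- rep(TRUE, nrow(pir$samples))
  if (!is.null(fraction)) keep <- keep & pir$samples$fraction %in% fraction
  if (!is.null(genotype)) keep <- keep & pir$samples$genotype %in% genotype
  if (!is.null(div_day)) keep <- keep & pir$samples$div_day %in% div_day
  if (!any(keep)) stop_irtax("no samples match the filter", "irtax_design_error")
  s <- pir$samples[keep, , drop = FALSE]
  attr(s, "design_days") <- attr(pir$samples, "design_days")
  class(s) <- class(pir$samples)
  v <- pir$values[, keep, drop = FALSE]
  if (!is.null(introns)) v <- v[introns, , drop = FALSE]
  pir_matrix(v, s)
}

#' Per-condition mean PIR
#'
#' Means are taken pairwise over non-missing values; the effective n per cell
#' is returned as an attribute.
#'
#' @param pir an `irtax_pir` object.
#' @return introns x conditions matrix of means with attribute `"n"` (counts
#'   of non-missing values entering each mean).
#' @export
condition_means <- function(pir) {
  cond <- condition_of(pir$samples)
  levs <- unique(cond)
  out <- matrix(NA_real_, nrow(pir$values), length(levs),
                dimnames = list(rownames(pir$values), levs))
  nmat <- matrix(0L, nrow(pir$values), length(levs),
                 dimnames = list(rownames(pir$values), levs))
  for (j in seq_along(levs)) {
    cols <- which(cond == levs[j])
    sub <- pir$values[, cols, drop = FALSE]
    nmat[, j] <- rowSums(!is.na(sub))
    out[, j] <- ifelse(nmat[, j] > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
  }
  attr(out, "n") <- nmat
  out
}

#' Read a PIR table (TSV) against a sample sheet
#'
#' Expects a tab-separated table whose header names the sample ids and whose
#' first column holds intron ids; cells are numeric PIR percentages or the
#' literal `NA`. Values are validated against `[0, 100]`; missing cells are
#' preserved as missing, never imputed.
#'
#' @param path file path.
#' @param samples the `irtax_samples` sheet the columns must match.
#' @return an `irtax_pir` object.
#' @export
read_pir_table <- function(path, samples) {
  df <- read_tsv_commented(path)
  if (ncol(df) < 2) stop_irtax("PIR table needs an id column and >= 1 sample",
                               "irtax_schema_error")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop_irtax("non-numeric PIR cells", "irtax_schema_error")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  unknown <- setdiff(colnames(m), samples$sample_id)
  if (length(unknown) > 0)
    stop_irtax(paste("unknown sample id(s) in PIR table:",
                     paste(unknown, collapse = ", ")), "irtax_schema_error")
  missing_cols <- setdiff(samples$sample_id, colnames(m))
  if (length(missing_cols) > 0)
    stop_irtax(paste("PIR table lacks sample(s):",
                     paste(missing_cols, collapse = ", ")), "irtax_schema_error")
  m <- m[, samples$sample_id, drop = FALSE]
  pir_matrix(m, samples)
}

#' Write a PIR matrix as TSV
#'
#' Values are written to six decimals; column order follows the sample sheet.
#'
#' @param pir an `irtax_pir` object.
#' @param path output file path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_pir_table <- function(pir, path, seed = NULL) {
  df <- data.frame(intron_id = rownames(pir$values),
                   round(pir$values, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, seed = seed)
}
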