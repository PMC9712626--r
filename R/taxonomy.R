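# The spatiotemporal taxonomy: decompose a compartment's PIR matrix by SVD,
# score every intron against each right singular vector (sample-space
# pattern) by Pearson correlation and projection, pick the extremes of each
# component with k-means, and assemble per-intron group labels across the
# two compartments.

#' Singular value decomposition of a PIR matrix
#'
#' Rows (introns) are optionally centered so components capture dynamics
#' rather than baseline PIR level. Missing values are imputed by the row
#' mean for the decomposition only (the imputation count is recorded);
#' downstream statistics keep the original values. Signs are fixed so that
#' each right singular vector's largest-magnitude entry is positive, making
#' the decomposition deterministic.
#'
#' @param pir an `irtax_pir` object.
#' @param centering `"row_center"` (default) or `"none"`.
#' @return list of class `irtax_svd`: `left_vectors` (introns x k),
#'   `singular_values`, `right_vectors` (samples x k), `variance_explained`,
#'   `centering`, `centered` (the matrix decomposed), `n_imputed`,
#'   `intron_ids`, `sample_ids`.
#' @export
svd_pir <- function(pir, centering = c("row_center", "none")) {
  centering <- match.arg(centering)
  x <- pir$values
  if (nrow(x) < 2 || ncol(x) < 2)
    stop_irtax("PIR matrix must have at least 2 rows and 2 columns",
               "irtax_shape_error")
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    rm <- rowMeans(x, na.rm = TRUE)
    rm[is.nan(rm)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm[idx[, 1]]
  }
  if (centering == "row_center") x <- x - rowMeans(x)
  s <- svd(x)
  flip <- vapply(seq_len(ncol(s$v)), function(k) {
    sign(s$v[which.max(abs(s$v[, k])), k])
  }, numeric(1))
  flip[flip == 0] <- 1
  s$v <- sweep(s$v, 2, flip, `*`)
  s$u <- sweep(s$u, 2, flip, `*`)
  structure(list(left_vectors = s$u, singular_values = s$d,
                 right_vectors = s$v,
                 variance_explained = s$d^2 / sum(s$d^2),
                 centering = centering, centered = x,
                 n_imputed = n_imputed,
                 intron_ids = rownames(pir$values),
                 sample_ids = colnames(pir$values)),
            class = "irtax_svd")
}

#' Score introns against one right singular vector
#'
#' For each intron, the Pearson correlation between its PIR profile and the
#' component's right singular vector, and the projection (inner product) of
#' its centered profile onto that vector. Zero-variance profiles get a
#' missing correlation and are excluded from extreme selection.
#'
#' @param pir an `irtax_pir` (used for the correlation on original values).
#' @param svd an `irtax_svd` from [svd_pir()].
#' @param component component index (1-based).
#' @return data.frame `intron_id`, `component_index`, `correlation`,
#'   `projection`.
#' @export
score_introns <- function(pir, svd, component) {
  if (component > length(svd$singular_values))
    stop_irtax("component exceeds the number of singular vectors",
               "irtax_config_error")
  v <- svd$right_vectors[, component]
  x <- pir$values
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  corr <- rep(NA_real_, nrow(x))
  ok <- !is.na(sds) & sds > 0
  corr[ok] <- suppressWarnings(
    as.numeric(stats::cor(t(x[ok, , drop = FALSE]), v,
                          use = "pairwise.complete.obs")))
  # centered profile rebuilt from the scored matrix (row-mean imputation as
  # in svd_pir), so scoring works for introns beyond the decomposed set
  xi <- x
  if (anyNA(xi)) {
    rm <- rowMeans(xi, na.rm = TRUE)
    rm[is.nan(rm)] <- 0
    idx <- which(is.na(xi), arr.ind = TRUE)
    xi[idx] <- rm[idx[, 1]]
  }
  if (svd$centering == "row_center") xi <- xi - rowMeans(xi)
  proj <- as.numeric(xi %*% v)
  data.frame(intron_id = rownames(x), component_index = component,
             correlation = corr, projection = proj,
             stringsAsFactors = FALSE)
}

#' Select the extreme introns of a component by k-means
#'
#' k-means (default k = 3, 20 restarts, fixed seed) on the standardized
#' (correlation, projection) pairs; the cluster whose centroid sum is largest
#' forms the positive set, the smallest the negative set, middle clusters are
#' unselected. Introns with missing correlation are excluded, and the
#' selected sets are restricted to introns whose profile correlates strongly
#' with the singular vector (`|correlation| >= min_abs_cor`): on components
#' that carry no temporal structure the score cloud is pure noise and its
#' k-means extremes would otherwise be reported as groups.
#'
#' @param scores data.frame from [score_introns()].
#' @param k_clusters number of clusters (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @param min_abs_cor minimum `|correlation|` for a selected intron
#'   (default 0.5).
#' @return list with `positive` and `negative` character vectors of intron
#'   ids.
#' @export
select_extremes <- function(scores, k_clusters = 3, seed = 1L,
                            min_abs_cor = 0.5) {
  sc <- scores[!is.na(scores$correlation) & is.finite(scores$projection), ]
  if (nrow(sc) < k_clusters)
    stop_irtax("fewer scored introns than clusters", "irtax_selection_error")
  z <- scale(cbind(sc$correlation, sc$projection))
  z[!is.finite(z)] <- 0  # constant column -> zero contribution
  if (nrow(unique(z)) < k_clusters)
    stop_irtax("fewer distinct score points than clusters",
               "irtax_selection_error")
  km <- with_seed(seed, stats::kmeans(z, centers = k_clusters, nstart = 20,
                                      iter.max = 50))
  csum <- rowSums(km$centers)
  strong <- abs(sc$correlation) >= min_abs_cor
  list(positive = sc$intron_id[km$cluster == which.max(csum) & strong &
                                 sc$correlation > 0],
       negative = sc$intron_id[km$cluster == which.min(csum) & strong &
                                 sc$correlation < 0])
}

resolve_components <- function(svd, n_components) {
  k_max <- sum(svd$singular_values > max(svd$singular_values) * 1e-10)
  if (identical(n_components, "auto")) {
    cv <- cumsum(svd$variance_explained)
    min(which(cv >= 0.6)[1], 5L, k_max)
  } else {
    if (n_components > k_max)
      stop_irtax("requested components exceed matrix rank", "irtax_config_error")
    as.integer(n_components)
  }
}

#' Assemble the spatiotemporal taxonomy across both compartments
#'
#' Runs [svd_pir()], [score_introns()] and [select_extremes()] per
#' compartment and component. Introns selected on any cytoplasmic component
#' form C-groups; introns selected only on nuclear components form N-groups;
#' each `(compartment, component, polarity)` triple maps to one group label.
#' An intron selected on several components of its compartment class is
#' resolved to the component where its projection is most extreme relative
#' to that component's projection spread (largest standardized
#' `|projection|`, matching the standardized space the k-means selection
#' operates in). Unselected introns are `unassigned`. Group names are
#' assigned deterministically in
#' `(component, polarity)` order: cytoplasmic labels `C1, C2, ...`, nuclear
#' labels `N1, N2, ...` (the names index recovered dynamics, not any fixed
#' external nomenclature).
#'
#' @param pir_nuc,pir_cyt `irtax_pir` matrices for the two compartments with
#'   matched intron sets.
#' @param n_components number of components per compartment (default 5), or
#'   `"auto"` for the smallest number explaining 60% of variance (capped
#'   at 5).
#' @param k_clusters,seed,min_abs_cor forwarded to [select_extremes()].
#' @param centering forwarded to [svd_pir()].
#' @return data.frame `intron_id`, `group`, `compartment`,
#'   `component_index`, `polarity`, `projection`, plus attribute
#'   `"svd"` (list with both decompositions).
#' @export
assign_taxonomy <- function(pir_nuc, pir_cyt, n_components = 5, k_clusters = 3,
                            seed = 1L, centering = "row_center",
                            min_abs_cor = 0.5) {
  if (!identical(rownames(pir_nuc$values), rownames(pir_cyt$values)))
    stop_irtax("intron sets must match across compartments", "irtax_schema_error")
  compartments <- list(nucleus = pir_nuc, cytoplasm = pir_cyt)
  cand <- list()
  svds <- list()
  for (comp_name in names(compartments)) {
    pir <- compartments[[comp_name]]
    sv <- svd_pir(pir, centering = centering)
    svds[[comp_name]] <- sv
    k <- resolve_components(sv, n_components)
    for (ci in seq_len(k)) {
      sc <- score_introns(pir, sv, ci)
      ex <- select_extremes(sc, k_clusters = k_clusters,
                            seed = child_seed(seed, 1000 * match(comp_name, names(compartments)) + ci),
                            min_abs_cor = min_abs_cor)
      proj <- stats::setNames(sc$projection, sc$intron_id)
      zproj <- stats::setNames(as.numeric(scale(sc$projection)), sc$intron_id)
      for (pol in c("positive", "negative")) {
        ids <- ex[[pol]]
        if (length(ids) == 0) next
        cand[[length(cand) + 1L]] <- data.frame(
          intron_id = ids, compartment = comp_name, component_index = ci,
          polarity = pol, projection = proj[ids], z_projection = zproj[ids],
          stringsAsFactors = FALSE)
      }
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(intron_id = character(), compartment = character(),
               component_index = integer(), polarity = character(),
               projection = numeric(), z_projection = numeric())

  all_ids <- rownames(pir_nuc$values)
  pick_best <- function(df) df[which.max(abs(df$z_projection)), , drop = FALSE]
  chosen <- do.call(rbind, lapply(split(cand, cand$intron_id), function(df) {
    cy <- df[df$compartment == "cytoplasm", , drop = FALSE]
    pick_best(if (nrow(cy) > 0) cy else df)
  }))

  out <- data.frame(intron_id = all_ids, group = "unassigned",
                    compartment = NA_character_, component_index = NA_integer_,
                    polarity = NA_character_, projection = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(chosen) && nrow(chosen) > 0) {
    # deterministic naming by (compartment, component, polarity)
    key <- sprintf("%s.%d.%s", chosen$compartment, chosen$component_index,
                   chosen$polarity)
    ord <- order(chosen$component_index,
                 match(chosen$polarity, c("positive", "negative")))
    label_for <- function(comp, prefix) {
      keys <- unique(key[ord][chosen$compartment[ord] == comp])
      stats::setNames(paste0(prefix, seq_along(keys)), keys)
    }
    labs <- c(label_for("cytoplasm", "C"), label_for("nucleus", "N"))
    m <- match(all_ids, chosen$intron_id)
    hit <- !is.na(m)
    out$group[hit] <- labs[key[m[hit]]]
    out$compartment[hit] <- chosen$compartment[m[hit]]
    out$component_index[hit] <- chosen$component_index[m[hit]]
    out$polarity[hit] <- chosen$polarity[m[hit]]
    out$projection[hit] <- chosen$projection[m[hit]]
  }
  attr(out, "svd") <- svds
  out
}

#' Adjusted Rand index between two labelings
#'
#' Standard permutation-adjusted agreement between two partitions of the
#' same items; 1 for identical partitions, ~0 at random.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
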