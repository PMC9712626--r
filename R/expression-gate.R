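#' Fit a two-component Gaussian mixture to log2 counts
#'
#' EM with unequal component variances, run to convergence (relative
#' log-likelihood change below `tol` or `max_iter` iterations). Components
#' are relabeled so that `mean_on > mean_off`. Initialization is
#' deterministic: component means at the 25th and 75th percentiles of the
#' data, equal weights, both sds at the overall sd; `seed` is only consumed
#' by optional random restarts.
#'
#' @param values numeric vector of log2 counts (>= 20 finite values).
#' @param seed integer, used only when `n_restarts > 0`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param n_restarts additional EM runs from randomly jittered starts; the
#'   best log-likelihood wins.
#' @return list of class `irtax_mixture`: `mean_off`, `mean_on`, `sd_off`,
#'   `sd_on`, `weight_on`, `responsibility_off` (per-value probability of the
#'   off component), `converged`, `n_iter`, `loglik_trace`.
#' @export
fit_two_component_mixture <- function(values, seed = 1L, tol = 1e-8,
                                      max_iter = 500L, n_restarts = 0L) {
  x <- values[is.finite(values)]
  if (length(x) < 20)
    stop_irtax("need >= 20 finite values for a mixture fit", "irtax_data_error")
  if (stats::sd(x) == 0)
    stop_irtax("degenerate input: all values identical", "irtax_degenerate_fit")

  run_em <- function(mu1, mu2, s1, s2, w2) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      d1 <- (1 - w2) * stats::dnorm(x, mu1, s1)
      d2 <- w2 * stats::dnorm(x, mu2, s2)
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      r2 <- d2 / tot
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      if (it >= max_iter) break
      ll_old <- ll
      w2 <- mean(r2)
      mu1 <- sum((1 - r2) * x) / sum(1 - r2)
      mu2 <- sum(r2 * x) / sum(r2)
      s1 <- sqrt(sum((1 - r2) * (x - mu1)^2) / sum(1 - r2))
      s2 <- sqrt(sum(r2 * (x - mu2)^2) / sum(r2))
      s1 <- max(s1, 1e-6)
      s2 <- max(s2, 1e-6)
    }
    list(mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2, w2 = w2, r2 = r2,
         ll = ll, trace = ll_trace, converged = converged, n_iter = it)
  }

  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  s0 <- stats::sd(x)
  best <- run_em(q[1], q[2], s0, s0, 0.5)
  if (n_restarts > 0) {
    with_seed(seed, {
      for (i in seq_len(n_restarts)) {
        st <- sort(sample(x, 2))
        cand <- run_em(st[1], st[2], s0, s0, stats::runif(1, 0.2, 0.8))
        if (cand$ll > best$ll) best <- cand
      }
    })
  }

  # order components so "on" is the one with the larger mean
  if (best$mu2 >= best$mu1) {
    resp_off <- 1 - best$r2
    out <- list(mean_off = best$mu1, mean_on = best$mu2,
                sd_off = best$s1, sd_on = best$s2, weight_on = best$w2)
  } else {
    resp_off <- best$r2
    out <- list(mean_off = best$mu2, mean_on = best$mu1,
                sd_off = best$s2, sd_on = best$s1, weight_on = 1 - best$w2)
  }
  resp_full <- rep(NA_real_, length(values))
  resp_full[is.finite(values)] <- resp_off
  structure(c(out, list(responsibility_off = resp_full,
                        converged = best$converged, n_iter = best$n_iter,
                        loglik_trace = best$trace)),
            class = "irtax_mixture")
}

#' Log2 transform of counts with a pseudocount of one
#'
#' @param counts non-negative numeric matrix or vector.
#' @return `log2(counts + 1)`.
#' @export
log2_counts <- function(counts) log2(counts + 1)

#' Call reliably expressed genes per condition
#'
#' A two-component mixture is fitted to every sample's log2 values; a gene is
#' reliably expressed in a condition (a `(fraction, div_day, genotype)`
#' triple) if and only if its probability of belonging to the non-expressed
#' component is below `alpha` in *every* sample of that condition. The union
#' across conditions defines the analysis gene universe.
#'
#' @param mat genes x samples matrix of log2 counts (gene rownames required).
#' @param samples an `irtax_samples` sheet matching `colnames(mat)`.
#' @param alpha off-component probability threshold (default 0.01).
#' @param seed forwarded to [fit_two_component_mixture()].
#' @return list with `expressed` (genes x conditions logical matrix),
#'   `universe` (character vector, union over conditions) and `fits`
#'   (per-sample mixture parameters, data.frame).
#' @export
call_expressed <- function(mat, samples, alpha = 0.01, seed = 1L) {
  if (!identical(colnames(mat), samples$sample_id))
    stop_irtax("matrix columns must match the sample sheet", "irtax_schema_error")
  cond <- condition_of(samples)
  if (any(table(cond) == 0))
    stop_irtax("condition with zero samples", "irtax_design_error")
  resp <- matrix(NA_real_, nrow(mat), ncol(mat),
                 dimnames = dimnames(mat))
  fits <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    f <- fit_two_component_mixture(mat[, j], seed = seed)
    resp[, j] <- f$responsibility_off
    fits[[j]] <- data.frame(sample_id = colnames(mat)[j],
                            mean_off = f$mean_off, mean_on = f$mean_on,
                            sd_off = f$sd_off, sd_on = f$sd_on,
                            weight_on = f$weight_on, converged = f$converged,
                            n_iter = f$n_iter, stringsAsFactors = FALSE)
  }
  levs <- unique(cond)
  expressed <- matrix(FALSE, nrow(mat), length(levs),
                      dimnames = list(rownames(mat), levs))
  for (lv in levs) {
    cols <- which(cond == lv)
    sub <- resp[, cols, drop = FALSE]
    expressed[, lv] <- rowSums(sub < alpha, na.rm = FALSE) == length(cols)
  }
  expressed[is.na(expressed)] <- FALSE
  list(expressed = expressed,
       universe = rownames(mat)[rowSums(expressed) > 0],
       fits = do.call(rbind, fits))
}
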