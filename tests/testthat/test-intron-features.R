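test_that("GC content handles N bases and rejects degenerate input", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_equal(gc_content("acgt"), 0.5)
  expect_error(gc_content("NNNN"), class = "irtax_undefined_feature")
  expect_error(gc_content("ACGU"), class = "irtax_format_error")
})

test_that("median conservation matches a per-base sort oracle", {
  mk <- function(start, end, score) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(start + 1L, end),
                           score = score)
  }
  expect_equal(median_conservation(mk(0, 100, 0.7), "chr1", 10, 60), 0.7)
  two <- c(mk(0, 50, 0), mk(50, 100, 1))
  expect_equal(median_conservation(two, "chr1", 0, 100), 0.5)
  expect_error(median_conservation(mk(0, 10, 1), "chr1", 500, 600),
               class = "irtax_undefined_feature")
  # < 50% coverage is undefined
  expect_error(median_conservation(mk(0, 10, 1), "chr1", 0, 100),
               class = "irtax_undefined_feature")

  for (s in 1:50) {
    withr::with_seed(s, {
      # non-overlapping segments, as in a bedGraph track
      brk <- sort(sample(0:100, 8))
      starts <- head(brk, -1)
      ends <- brk[-1]
      keep <- (ends > starts) & (runif(length(starts)) < 0.7)  # gaps allowed
      starts <- starts[keep]; ends <- ends[keep]
      sc <- round(runif(length(starts)), 3)
      q <- sort(sample(0:99, 2))
    })
    tr <- mk(starts, ends, sc)
    # brute-force per-base expansion
    base_scores <- rep(NA_real_, 100)
    for (i in seq_along(starts)) {
      base_scores[(starts[i] + 1):ends[i]] <- sc[i]
    }
    span <- (q[1] + 1):(q[2] + 1)
    span <- span[span <= 100]
    covered <- base_scores[span][!is.na(base_scores[span])]
    if (length(covered) >= 0.5 * length(span)) {
      v <- sort(covered)
      n <- length(v)
      brute <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
      expect_equal(median_conservation(tr, "chr1", q[1], q[2] + 1), brute)
    } else {
      expect_error(median_conservation(tr, "chr1", q[1], q[2] + 1),
                   class = "irtax_undefined_feature")
    }
  }
})

test_that("the 50-nt rule distinguishes premature from terminal stops", {
  # exon1 (ATG...) | intron with in-frame TAA | exon2 long | exon3
  exons <- c(paste0("ATG", strrep("GCA", 10)),  # 33 nt
             strrep("GCT", 40),                 # 120 nt
             strrep("GGA", 10))                 # 30 nt
  intron <- paste0(strrep("GCC", 5), "TAA", strrep("GCG", 10))
  res <- ptc_scan(exons, intron, intron_after = 1, cds_start = 1)
  expect_true(res$has_ptc)  # stop inside the intron, far from the last junction
  expect_gt(res$last_junction - (res$stop_position + 2), 50)

  # stop only near the end: within 50 nt of the final junction -> no PTC
  exons2 <- c(paste0("ATG", strrep("GCA", 10)),
              paste0(strrep("GCT", 12), "TAA"),  # stop at the end of exon 2
              strrep("GGA", 10))
  intron2 <- strrep("GCC", 10)  # no stop, keeps frame
  res2 <- ptc_scan(exons2, intron2, intron_after = 1, cds_start = 1)
  expect_false(res2$has_ptc)
  expect_false(is.na(res2$stop_position))

  expect_error(ptc_scan(exons, intron, 1, cds_start = 5),
               class = "irtax_annotation_error")
})

test_that("ptc_scan agrees with a translation oracle on random transcripts", {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  for (s in 1:50) {
    withr::with_seed(200 + s, {
      n_ex <- sample(2:4, 1)
      exons <- vapply(seq_len(n_ex), function(i)
        paste(sample(codons, sample(8:20, 1), replace = TRUE), collapse = ""),
        character(1))
      exons[1] <- paste0("ATG", exons[1])
      intron <- paste(sample(codons, sample(5:15, 1), replace = TRUE),
                      collapse = "")
      after <- sample(seq_len(n_ex - 1), 1)
    })
    res <- ptc_scan(exons, intron, intron_after = after, cds_start = 1)

    # oracle: translate the retained transcript with Biostrings and find the
    # first stop; apply the 50-nt rule against the last junction
    pieces <- append(exons, intron, after = after)
    tx <- paste(pieces, collapse = "")
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(tx, 1, nchar(tx) - nchar(tx) %% 3)),
      if.fuzzy.codon = "X"))
    stop_aa <- regexpr("*", aa, fixed = TRUE)[[1]]
    ends <- cumsum(nchar(pieces))
    jx <- ends[setdiff(seq_len(length(pieces) - 1),
                       if (after > 0) after + 1 else integer(0))]
    jx <- jx[jx != ends[after]]  # retained boundary is not a junction
    last_j <- if (length(jx)) max(jx) else NA
    if (stop_aa == -1) {
      expect_false(res$has_ptc)
    } else {
      stop_start <- (stop_aa - 1) * 3 + 1
      expect_equal(res$stop_position, stop_start)
      expected <- !is.na(last_j) && (last_j - (stop_start + 2)) > 50
      expect_equal(res$has_ptc, expected)
    }
  }
})

test_that("feature ANOVA F statistics match a normal-equations oracle", {
  for (s in 1:50) {
    withr::with_seed(300 + s, {
      n <- 60
      f <- data.frame(length_feature = rnorm(n), gc = runif(n),
                      conservation_median = runif(n),
                      rbp_enrichment = rexp(n), n_introns_in_gene = rpois(n, 5) + 1)
      y <- rnorm(n, 2 * f$gc)
    })
    res <- pir_feature_anova(f, y)
    x <- scale(as.matrix(f))
    X <- cbind(1, x)
    rss <- function(X) {
      beta <- solve(t(X) %*% X, t(X) %*% y)
      sum((y - X %*% beta)^2)
    }
    rss_full <- rss(X)
    for (j in seq_len(ncol(x))) {
      rss_red <- rss(X[, -(j + 1), drop = FALSE])
      f_oracle <- (rss_red - rss_full) / (rss_full / (nrow(X) - ncol(X)))
      expect_equal(res$f_statistic[j], f_oracle, tolerance = 1e-8)
    }
  }
})

test_that("a feature driving the response is detected; pure noise is not", {
  withr::with_seed(99, {
    n <- 500
    f <- data.frame(length_feature = rnorm(n), gc = runif(n),
                    conservation_median = runif(n),
                    rbp_enrichment = rexp(n),
                    n_introns_in_gene = rpois(n, 5) + 1)
    y <- 5 * f$gc + rnorm(n, 0, 0.1)
  })
  res <- pir_feature_anova(f, y)
  expect_lt(res$p_value[res$feature_name == "gc"], 1e-6)
  expect_gt(min(res$p_value[res$feature_name != "gc"]), 1e-4)
})

test_that("constant and collinear features raise informative errors", {
  withr::with_seed(7, {
    f <- data.frame(length_feature = rnorm(30), gc = runif(30),
                    conservation_median = 0.5,
                    rbp_enrichment = rexp(30), n_introns_in_gene = rpois(30, 4) + 1)
  })
  err <- expect_error(pir_feature_anova(f, rnorm(30)),
                      class = "irtax_collinearity_error")
  expect_match(conditionMessage(err), "conservation_median")
  f$conservation_median <- f$gc  # exact duplicate
  expect_error(pir_feature_anova(f, rnorm(30)), class = "irtax_collinearity_error")
})

test_that("the assembled feature table carries both length transforms", {
  cfg <- fast_config(seed = 41)
  genome <- simulate_genome_and_introns(cfg)
  focal <- genome$introns[match(genome$focal$intron_id, genome$introns$intron_id), ]
  ft <- intron_feature_table(focal, genome$sequences, all_introns = genome$introns)
  expect_equal(ft$length_feature, log10(ft$length_nt))
  expect_true(all(ft$gc > 0 & ft$gc < 1))
  expect_true(all(ft$n_introns_in_gene >= 2))
  ft2 <- intron_feature_table(focal, genome$sequences, all_introns = genome$introns,
                              length_transform = "logit")
  expect_true(all(is.finite(ft2$length_feature)))
})
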