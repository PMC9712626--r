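mk_track <- function(rbp, chrom, pos, strand) crosslink_track(rbp, chrom, pos, strand)

test_that("region definitions match the hand-computed plus-strand layout", {
  ints <- intron_records("i1", "g1", "chr1", 1000L, 1200L, "+", 900L, 1300L)
  r <- define_regions(ints)
  expect_true(all(r$valid))
  got <- setNames(split(r[, c("start", "end")], r$region), NULL)
  expect_equal(r$start[r$region == "R1"], 970L)
  expect_equal(r$end[r$region == "R1"], 1000L)
  expect_equal(r$start[r$region == "R2"], 1000L)
  expect_equal(r$end[r$region == "R2"], 1030L)
  expect_equal(r$start[r$region == "R3"], 1085L)
  expect_equal(r$end[r$region == "R3"], 1115L)
  expect_equal(r$start[r$region == "R4"], 1170L)
  expect_equal(r$end[r$region == "R4"], 1200L)
  expect_equal(r$start[r$region == "R5"], 1200L)
  expect_equal(r$end[r$region == "R5"], 1230L)
  expect_true(all(r$end - r$start == 30L))
})

test_that("short introns and short exons flag regions invalid", {
  ints <- intron_records("i1", "g1", "chr1", 1000L, 1060L, "+", 900L, 1300L)
  r <- define_regions(ints)
  expect_false(any(r$valid[r$region %in% c("R2", "R3", "R4")]))
  expect_true(all(r$valid[r$region %in% c("R1", "R5")]))

  ints2 <- intron_records("i2", "g1", "chr1", 1000L, 1200L, "+", 980L, 1300L)
  r2 <- define_regions(ints2)
  expect_false(r2$valid[r2$region == "R1"])  # upstream exon only 20 nt
  expect_true(r2$valid[r2$region == "R5"])
})

test_that("minus-strand regions mirror the plus-strand computation", {
  plus <- intron_records("p", "g1", "chr1", 1000L, 1200L, "+", 900L, 1300L)
  minus <- intron_records("m", "g1", "chr1", 1000L, 1200L, "-", 900L, 1300L)
  rp <- define_regions(plus)
  rm_ <- define_regions(minus)
  # mirror map: R1<->R1 reflected about the intron: R1 on minus sits where a
  # plus-strand R5 would, etc.; R3 is central and identical
  flip <- c(R1 = "R5", R2 = "R4", R3 = "R3", R4 = "R2", R5 = "R1")
  for (reg in names(flip)) {
    a <- rm_[rm_$region == reg, ]
    b <- rp[rp$region == flip[[reg]], ]
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
  }
})

test_that("hit matrices respect region membership and strand", {
  ints <- intron_records("i1", "g1", "chr1", 1000L, 1200L, "+", 900L, 1300L)
  r <- define_regions(ints)
  tr <- mk_track("A", "chr1", 1005L, "+")  # inside R2
  h <- build_hit_matrix(list(tr), r, ints)
  expect_true(h$hits["i1", "A", "R2"])
  expect_true(h$hits["i1", "A", "intron"])
  expect_false(any(h$hits["i1", "A", c("R1", "R3", "R4", "R5")]))
  # opposite strand: no hit
  h2 <- build_hit_matrix(list(mk_track("A", "chr1", 1005L, "-")), r, ints)
  expect_false(any(h2$hits["i1", "A", ], na.rm = TRUE))
  # unknown chromosome: warning, event skipped
  expect_warning(
    h3 <- build_hit_matrix(list(mk_track("A", "chrZ", 5L, "+")), r, ints),
    "unknown chromosome")
  expect_equal(h3$n_skipped, 1L)
})

test_that("random hit matrices equal an interval-membership loop oracle", {
  cfg <- fast_config(seed = 51)
  genome <- simulate_genome_and_introns(cfg)
  ints <- genome$introns[1:40, ]
  regions <- define_regions(ints)
  withr::with_seed(52, {
    pos <- sample(0:max(ints$end), 1000, replace = TRUE)
    str <- sample(c("+", "-"), 1000, replace = TRUE)
  })
  tr <- mk_track("X", "chrS", pos, str)
  h <- build_hit_matrix(list(tr), regions, ints)
  for (i in sample(nrow(ints), 10)) {
    for (reg in c("R1", "R2", "R3", "R4", "R5")) {
      rr <- regions[regions$intron_id == ints$intron_id[i] & regions$region == reg, ]
      oracle <- if (!rr$valid) NA else
        any(tr$position >= rr$start & tr$position < rr$end &
              tr$strand == rr$strand & tr$chrom == rr$chrom)
      expect_identical(unname(h$hits[ints$intron_id[i], "X", reg]), oracle)
    }
    oracle_n <- sum(tr$position >= ints$start[i] & tr$position < ints$end[i] &
                      tr$strand == ints$strand[i])
    expect_equal(unname(h$counts[ints$intron_id[i], "X"]), oracle_n)
  }
})

test_that("enrichment scores follow the fraction-ratio definition", {
  # forced arithmetic: group 4/10 hit vs background 20/100 hit -> 2.0
  ids <- sprintf("i%03d", 1:100)
  hits <- array(FALSE, c(100, 1, 6),
                dimnames = list(ids, "A", c("R1", "R2", "R3", "R4", "R5", "intron")))
  hits[1:20, 1, "intron"] <- TRUE   # 20/100 background hits
  grp <- c(ids[1:4], ids[30:35])    # 4 of 10 hit
  h <- structure(list(hits = hits, counts = NULL, n_skipped = 0L),
                 class = "irtax_hits")
  e <- group_enrichment(h, grp, ids, scope = "intron")
  expect_equal(e$enrichment, 2.0)
  # identity case
  e2 <- group_enrichment(h, ids, ids, scope = "intron")
  expect_equal(e2$enrichment, 1.0)
  # zero background fraction -> undefined
  hits0 <- hits; hits0[, , "intron"] <- FALSE
  h0 <- structure(list(hits = hits0, counts = NULL, n_skipped = 0L),
                  class = "irtax_hits")
  expect_true(is.na(group_enrichment(h0, grp, ids, scope = "intron")$enrichment))
  expect_error(group_enrichment(h, c("nope"), ids), class = "irtax_config_error")
})

test_that("Fisher p-values equal hypergeometric tail enumeration on small tables", {
  hyper_tail <- function(k_g, n_g, k_b, n_b) {
    # P(X >= k_g) with X ~ Hypergeom(total hits k_b, group size n_g, total n_b)
    sum(dhyper(k_g:min(n_g, k_b), k_b, n_b - k_b, n_g))
  }
  for (s in 1:50) {
    withr::with_seed(400 + s, {
      n_b <- sample(8:30, 1)
      n_g <- sample(2:(n_b - 2), 1)
      hit <- rbinom(n_b, 1, runif(1, 0.2, 0.8)) == 1
    })
    ids <- sprintf("i%02d", seq_len(n_b))
    hits <- array(FALSE, c(n_b, 1, 6),
                  dimnames = list(ids, "A", c("R1", "R2", "R3", "R4", "R5", "intron")))
    hits[hit, 1, "intron"] <- TRUE
    h <- structure(list(hits = hits, counts = NULL, n_skipped = 0L),
                   class = "irtax_hits")
    grp <- ids[seq_len(n_g)]
    e <- group_enrichment(h, grp, ids, scope = "intron")
    expect_equal(e$p_value, hyper_tail(sum(hit[seq_len(n_g)]), n_g, sum(hit), n_b),
                 tolerance = 1e-10)
  }
})

test_that("per-intron enrichment is a length-normalized rate ratio", {
  ints <- intron_records(c("a", "b", "c"), "g1", "chr1",
                         c(0L, 200L, 400L), c(100L, 300L, 500L), "+",
                         c(-50L, 150L, 350L), c(150L, 350L, 550L))
  # equal per-nt rates: 2 events/100nt everywhere
  tr <- mk_track("A", "chr1", c(10L, 50L, 210L, 250L, 410L, 450L), "+")
  expect_equal(per_intron_enrichment(list(tr), ints[1, ], ints[2:3, ]), 1.0)
  # intron rate 0.04 vs background 0.02 -> 2.0
  tr2 <- mk_track("A", "chr1", c(10L, 30L, 50L, 70L, 210L, 250L, 410L, 450L), "+")
  expect_equal(per_intron_enrichment(list(tr2), ints[1, ], ints[2:3, ]), 2.0)
  # zero background rate -> undefined
  tr3 <- mk_track("A", "chr1", c(10L), "+")
  expect_true(is.na(per_intron_enrichment(list(tr3), ints[1, ], ints[2:3, ])))
  expect_error(per_intron_enrichment(list(tr), ints[1, ], ints[0, ]),
               class = "irtax_undefined_feature")

  # random placements match a counting oracle
  for (s in 1:10) {
    withr::with_seed(500 + s, {
      pos <- sample(0:499, 60, replace = FALSE)
    })
    trk <- mk_track("A", "chr1", pos, "+")
    n_in <- function(rows) sum(pos >= rep(rows$start, each = length(pos)) &
                                 pos < rep(rows$end, each = length(pos)))
    n_a <- sum(pos >= 0 & pos < 100)
    n_bc <- sum(pos >= 200 & pos < 300) + sum(pos >= 400 & pos < 500)
    oracle <- (n_a / 100) / (n_bc / 200)
    got <- per_intron_enrichment(list(trk), ints[1, ], ints[2:3, ])
    if (n_bc == 0) expect_true(is.na(got)) else expect_equal(got, oracle)
  }
})

test_that("significant RBP selection requires enrichment, not depletion", {
  tab <- data.frame(group = "C5", rbp = c("A", "B", "C"), scope = "intron",
                    fraction_group = c(0.6, 0.1, 0.5),
                    fraction_background = c(0.4, 0.2, 0.45),
                    enrichment = c(1.5, 0.5, 1.1),
                    p_value = c(0.005, 0.005, 0.5))
  sig <- significant_rbps(tab, alpha = 0.01)
  expect_equal(sig$C5, "A")  # B is depleted, C not significant
})

test_that("group clustering is deterministic and order-invariant", {
  withr::with_seed(61, {
    a <- runif(10, 1, 2)
    tab <- rbind(
      data.frame(group = "A", rbp = sprintf("r%02d", 1:10), scope = "R2",
                 enrichment = a),
      data.frame(group = "B", rbp = sprintf("r%02d", 1:10), scope = "R2",
                 enrichment = a),                     # identical to A
      data.frame(group = "C", rbp = sprintf("r%02d", 1:10), scope = "R2",
                 enrichment = a + 5))                 # distant
  })
  hc <- cluster_groups(tab, scopes = "R2")
  m <- hc$merge
  first <- sort(hc$labels[-m[1, ]])
  expect_equal(first, c("A", "B"))
  expect_equal(hc$height[1], 0)

  tab_perm <- tab[withr::with_seed(3, sample(nrow(tab))), ]
  hc2 <- cluster_groups(tab_perm, scopes = "R2")
  expect_identical(stats::cophenetic(hc), stats::cophenetic(hc2))
  expect_error(cluster_groups(tab[tab$group == "A", ], scopes = "R2"),
               class = "irtax_clustering_error")
})

test_that("background self-enrichment is exactly 1 for every RBP and scope", {
  cfg <- fast_config(seed = 71, p0 = 0.3)
  genome <- simulate_genome_and_introns(cfg)
  truth <- data.frame(intron_id = genome$focal$intron_id, group = genome$focal$group)
  xl <- simulate_crosslinks(cfg, genome, truth)
  hits <- build_hit_matrix(xl$tracks, define_regions(genome$introns), genome$introns)
  bg <- genome$focal$intron_id
  for (sc in c("R1", "R3", "intron")) {
    e <- group_enrichment(hits, bg, bg, scope = sc)
    expect_true(all(e$enrichment[!is.na(e$enrichment)] == 1))
  }
})
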