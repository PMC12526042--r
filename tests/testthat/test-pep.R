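# pEP pair construction, flagging, pair statistics, enrichment, Fisher
# test, permutation test, top-fraction filtering.

test_that("pair construction is per-transcript with >=1 bp overlap", {
  # one gene, two transcripts sharing a TSS, one overlapping pELS -> 2 pairs
  tx <- gintervals("chr1", c(10000, 10000), c(13000, 14000), strand = "+")
  S4Vectors::mcols(tx)$gene_id <- "g1"
  S4Vectors::mcols(tx)$transcript_id <- c("g1.t1", "g1.t2")
  ts <- transcript_set(tx)
  pels <- gintervals("chr1", 8800, 9100)  # overlaps [9000, 10200) by 100 bp
  S4Vectors::mcols(pels)$class <- "pELS"
  pairs <- build_pep_pairs(ts, pels)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$transcript_id, c("g1.t1", "g1.t2"))
  # half-open adjacency is not an overlap: pELS ending at promoter start
  adj <- gintervals("chr1", 8800, 9000)
  S4Vectors::mcols(adj)$class <- "pELS"
  expect_equal(nrow(build_pep_pairs(ts, adj)), 0L)
  # dELS are never paired
  dels <- gintervals("chr1", 9000, 9300)
  S4Vectors::mcols(dels)$class <- "dELS"
  expect_equal(nrow(build_pep_pairs(ts, dels)), 0L)
  expect_error(build_pep_pairs(ts, gintervals("chr1", 0, 1)), "class")
})

test_that("GQ flags honor flank semantics and monotonicity", {
  tx <- gintervals("chr1", 10000, 13000, strand = "+")
  S4Vectors::mcols(tx)$gene_id <- "g1"
  S4Vectors::mcols(tx)$transcript_id <- "g1.t1"
  ts <- transcript_set(tx)
  pels <- gintervals("chr1", 9500, 9700)  # inside the promoter window
  S4Vectors::mcols(pels)$class <- "pELS"
  pairs <- build_pep_pairs(ts, pels)
  # GQ 50 bp outside the promoter: flank 0 misses, flank 100 hits
  gq_out <- gintervals("chr1", 8930, 8950)  # promoter starts at 9000
  expect_false(flag_gq(pairs, gq_out, flank = 0)$gq_in_promoter)
  expect_true(flag_gq(pairs, gq_out, flank = 100)$gq_in_promoter)
  # one GQ inside a pELS nested in the promoter sets both flags
  gq_in <- gintervals("chr1", 9550, 9570)
  f <- flag_gq(pairs, gq_in)
  expect_true(f$gq_in_promoter && f$gq_in_enhancer)
  # monotone in flank
  set.seed(41)
  w <- small_world(seed = 12L)
  pw <- build_pep_pairs(w$ann$tx_set, w$ann$ccres)
  gq <- bed_df_to_gr(random_intervals_df(60, w$ann$chrom_sizes, 25))
  f0 <- flag_gq(pw, gq, 0); f100 <- flag_gq(pw, gq, 100)
  expect_true(all(f100$gq_in_promoter[f0$gq_in_promoter]))
  expect_true(all(f100$gq_in_enhancer[f0$gq_in_enhancer]))
  expect_error(flag_gq(pairs, gq_in, flank = -1), ">= 0")
})

test_that("pair statistics satisfy the count inequalities on random data", {
  for (seed in c(3L, 8L)) {
    w <- small_world(seed = seed)
    pairs <- build_pep_pairs(w$ann$tx_set, w$ann$ccres)
    set.seed(seed)
    gq <- bed_df_to_gr(random_intervals_df(80, w$ann$chrom_sizes, 25))
    st <- pair_stats(flag_gq(pairs, gq), gq)
    cnt <- setNames(st$pairs$count, st$pairs$statistic)
    expect_lte(cnt[["gq_both"]],
               min(cnt[["gq_promoter"]], cnt[["gq_enhancer"]]))
    expect_lte(max(cnt), st$n_pairs)
    gcnt <- setNames(st$genes$count, st$genes$statistic)
    expect_lte(gcnt[["gq_both"]],
               min(gcnt[["gq_promoter"]], gcnt[["gq_enhancer"]]))
    expect_lte(max(gcnt), st$n_genes)
    expect_true(all(st$gq$count <= st$gq$total))
  }
  # no enhancer GQ: both-share 0, promoter rows unaffected. A TSS-local GQ
  # sits inside the promoter window but far from any (upstream) pELS.
  w <- small_world(seed = 5L)
  pairs <- build_pep_pairs(w$ann$tx_set, w$ann$ccres)
  prom_only_gq <- GenomicRanges::resize(tss_of(w$ann$tx_set)[1], 20L,
                                        fix = "center")
  st <- pair_stats(flag_gq(pairs, prom_only_gq))
  expect_equal(st$pairs$count[st$pairs$statistic == "gq_both"], 0L)
})

test_that("a count-reconstructed universe reproduces published-style shares", {
  pairs <- pair_universe_from_counts(
    n_pairs = 212825, n_promoter = 169020, n_enhancer = 75254,
    n_both = 71799, n_genes = 24142, n_genes_promoter = 17739,
    n_genes_enhancer = 13045, n_genes_both = 12318
  )
  st <- pair_stats(pairs)
  expect_equal(round(100 * st$pairs$share, 2), c(79.42, 35.36, 33.74))
  expect_equal(round(100 * st$genes$share, 2), c(73.48, 54.03, 51.02))
  expect_equal(st$n_genes, 24142L)
})

test_that("enrichment ratio and Fisher test behave on edge universes", {
  # all pairs flagged both: observed = expected = ratio = 1, degenerate
  allboth <- pair_universe_from_counts(50, 50, 50, 50)
  e <- enrichment(allboth)
  expect_equal(c(e$observed_share, e$expected_share, e$ratio), c(1, 1, 1))
  expect_true(e$degenerate)
  expect_equal(e$fisher_p, 1)
  mixed <- pair_universe_from_counts(100, 50, 40, 30)
  em <- enrichment(mixed)
  expect_equal(em$ratio, 0.30 / (0.5 * 0.4))
  expect_false(em$degenerate)
})

test_that("fisher_exact matches full enumeration for small tables", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  t10 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact(t10)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact(t10)$odds_ratio, Inf)
  set.seed(47)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    got <- fisher_exact(tab)
    expect_equal(got$p_value, oracle_fisher_p(tab), tolerance = 1e-9)
    # row swap leaves p unchanged
    expect_equal(fisher_exact(tab[2:1, ])$p_value, got$p_value)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    if (b * c > 0) expect_equal(got$odds_ratio, a * d / (b * c))
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("permutation enrichment detects identity and respects the seed", {
  set.seed(51)
  sizes <- c(chr1 = 50000)
  q <- bed_df_to_gr(random_intervals_df(40, sizes, 30))
  r1 <- permutation_enrichment(q, q, sizes, n_perm = 99, seed = 7L)
  expect_equal(r1$observed, 40L)
  expect_gt(r1$fold, 1)
  expect_equal(r1$p, 1 / 100)
  expect_equal(r1, permutation_enrichment(q, q, sizes, n_perm = 99, seed = 7L))
  # duplicating subjects does not change the fold (overlap is binary)
  s <- bed_df_to_gr(random_intervals_df(60, sizes, 50))
  f1 <- permutation_enrichment(q, s, sizes, n_perm = 99, seed = 3L)
  f2 <- permutation_enrichment(q, c(s, s), sizes, n_perm = 99, seed = 3L)
  expect_equal(f1$fold, f2$fold)
  expect_error(
    permutation_enrichment(gintervals("chr1", 0, 60000), s,
                           sizes, n_perm = 9),
    "past chromosome end")
})

test_that("top_fraction selects by score with coordinate tie-breaks", {
  set.seed(53)
  els <- bed_df_to_gr(random_intervals_df(100, c(chr1 = 100000), 50))
  S4Vectors::mcols(els)$score <- round(runif(100), 3)
  top <- top_fraction(els, 0.05)
  expect_length(top, 5L)
  expect_equal(sort(S4Vectors::mcols(top)$score, decreasing = TRUE),
               sort(S4Vectors::mcols(els)$score, decreasing = TRUE)[1:5])
  # equal scores: first k in coordinate order
  S4Vectors::mcols(els)$score <- 1
  tied <- top_fraction(els, 0.1)
  orded <- els[order(as.character(GenomicRanges::seqnames(els)),
                     GenomicRanges::start(els))]
  expect_equal(gr_to_bed_df(tied), gr_to_bed_df(orded[1:10]))
  # frac = 1 returns everything; missing scores error
  expect_length(top_fraction(els, 1), 100L)
  S4Vectors::mcols(els)$score <- NULL
  expect_error(top_fraction(els), "score")
})

test_that("element-level expected share counts each element once", {
  # two transcripts sharing one promoter-overlapping pELS: pair-level and
  # element-level expectations differ when flags are unbalanced
  pairs <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    transcript_id = c("t1", "t2", "t3"),
    chrom = "chr1",
    prom_start = c(0, 0, 500), prom_end = c(100, 100, 600),
    enh_id = c("e1", "e1", "e2"),
    enh_start = c(50, 50, 550), enh_end = c(80, 80, 580),
    gq_in_promoter = c(TRUE, TRUE, FALSE),
    gq_in_enhancer = c(TRUE, TRUE, FALSE)
  )
  class(pairs) <- c("pep_pairs", "data.frame")
  ep <- enrichment(pairs, expected = "pair")
  ee <- enrichment(pairs, expected = "element")
  expect_equal(ep$expected_share, (2 / 3)^2)
  # distinct elements: promoters {0-100, 500-600}, enhancers {e1, e2}
  expect_equal(ee$expected_share, (1 / 2)^2)
  expect_equal(ep$observed_share, ee$observed_share)
})
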