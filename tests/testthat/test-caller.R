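# Canonical motif scanner, window scoring, genome calling, evaluation.

test_that("scanner handles the canonical worked examples", {
  m <- find_canonical_motifs("GGGAGGGAGGGAGGG", both_strands = FALSE)
  expect_length(m, 1L)
  expect_equal(S4Vectors::mcols(m)$runs, "3,3,3,3")
  expect_equal(S4Vectors::mcols(m)$loops, "1,1,1")
  expect_equal(GenomicRanges::width(m), 15L)

  expect_length(find_canonical_motifs(strrep("G", 12)), 0L)

  rc <- find_canonical_motifs("CCCTCCCTCCCTCCC")
  expect_length(rc, 1L)
  expect_equal(as.character(GenomicRanges::strand(rc)), "-")
  expect_equal(GenomicRanges::width(rc), 15L)

  expect_error(find_canonical_motifs("GGGXGGG"), "non-DNA")
  # N may appear in loops but never counts toward a G-run
  withN <- find_canonical_motifs("GGGNGGGNGGGNGGG", both_strands = FALSE)
  expect_length(withN, 1L)
  expect_length(find_canonical_motifs("GGNGGGNGGGNGGGG",
                                      both_strands = FALSE), 0L)
})

test_that("scanner agrees with the anchored-regex oracle on random strings", {
  set.seed(19)
  n_checked <- 0L
  for (i in 1:400) {
    s <- random_scan_string()
    want <- oracle_scan_both(s)
    got <- find_canonical_motifs(s)
    expect_equal(length(got), nrow(want), info = s)
    if (nrow(want)) {
      got_df <- data.frame(start = GenomicRanges::start(got),
                           end = GenomicRanges::end(got),
                           strand = as.character(GenomicRanges::strand(got)))
      got_df <- got_df[order(got_df$start, got_df$strand), ]
      expect_equal(got_df, want, ignore_attr = TRUE, info = s)
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 50)  # the corpus must actually exercise matches
})

test_that("default window score reflects central motif coverage", {
  bg <- strrep("A", 512)
  expect_equal(default_window_score(bg), 0)
  motif <- "GGGAGGGAGGGAGGG"  # 15 bp
  centered <- paste0(strrep("A", 248), motif, strrep("A", 512 - 248 - 15))
  expect_equal(default_window_score(centered), 1)
  expect_gte(default_window_score(centered), 0.25)
  # a motif outside the central 128 bp contributes nothing
  edge <- paste0(motif, strrep("A", 512 - 15))
  expect_equal(default_window_score(edge), 0)
  # monotone: more central motif bases never decrease the score
  two <- paste0(strrep("A", 200), motif, strrep("T", 30), motif,
                strrep("A", 512 - 200 - 30 - 30))
  expect_gte(default_window_score(two), default_window_score(centered))
  expect_error(default_window_score("ACGT"), "512")
})

test_that("genome calling is deterministic and respects min_len", {
  cfg <- synth_config(genome_length = 60000L, n_chroms = 1L,
                      n_planted_gq = 15L, seed = 14L)
  g <- gen_genome(cfg)
  calls1 <- call_genome(g$genome)
  calls2 <- call_genome(g$genome)
  expect_equal(gr_to_bed_df(calls1), gr_to_bed_df(calls2))
  expect_true(all(GenomicRanges::width(calls1) >= 15))
  # every call contains planted motif support
  expect_equal(count_overlapping(calls1, g$truth)$fraction, 1.0)
  # a motif-free genome yields no calls
  cfg0 <- synth_config(genome_length = 30000L, n_chroms = 1L,
                       n_planted_gq = 0L, gc_content = 0.3, seed = 2L)
  g0 <- gen_genome(cfg0)
  expect_length(call_genome(g0$genome), 0L)
  # chromosomes shorter than one window are skipped with a warning
  tiny <- Biostrings::DNAStringSet(c(chrS = strrep("A", 100)))
  expect_warning(call_genome(tiny), "skipped")
})

test_that("a single interior motif yields exactly one covering call", {
  motif <- "GGGTTGGGTTGGGTTGGG"
  s <- paste0(strrep("A", 700), motif, strrep("T", 1400 - 700 - nchar(motif)))
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  calls <- call_genome(genome, call_params(stride = 128L))
  expect_length(calls, 1L)
  expect_equal(GenomicRanges::start(calls), 701L)
  expect_equal(GenomicRanges::width(calls), nchar(motif))
  expect_equal(as.character(GenomicRanges::strand(calls)), "+")
})

test_that("an imported score track can replace the scorer", {
  s <- strrep("A", 1024)
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  track <- gintervals("chr1", c(0, 192), c(512, 704), score = c(0.9, 0.1))
  calls <- call_genome(genome, score_track = track)
  # only the first placement passes the threshold; no motif support, so the
  # merged center region itself is returned
  expect_length(calls, 1L)
  expect_equal(gr_to_bed_df(calls)[c("start", "end")],
               data.frame(start = 192L, end = 320L))
  expect_equal(S4Vectors::mcols(calls)$score, 0.9)
})

test_that("evaluation matches a per-base confusion oracle", {
  set.seed(23)
  sizes <- c(chr1 = 20000, chr2 = 20000)
  pred <- bed_df_to_gr(random_intervals_df(200, sizes, max_width = 40))
  truth <- bed_df_to_gr(random_intervals_df(200, sizes, max_width = 40))
  ev <- evaluate_calls(pred, truth, sizes)
  pm <- mask_from_df(gr_to_bed_df(pred), sizes)
  tm <- mask_from_df(gr_to_bed_df(truth), sizes)
  p <- unlist(pm); t <- unlist(tm)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  expect_equal(ev$base$precision, tp / (tp + fp))
  expect_equal(ev$base$recall, tp / (tp + fn))
  expect_equal(ev$base$accuracy, (tp + tn) / sum(sizes))
  # interval-level oracle via the O(nm) scan
  expect_equal(ev$interval$precision,
               oracle_count_overlapping(gr_to_bed_df(pred),
                                        gr_to_bed_df(truth))$fraction)
  expect_equal(ev$interval$recall,
               oracle_count_overlapping(gr_to_bed_df(truth),
                                        gr_to_bed_df(pred))$fraction)
  # edge cases
  perfect <- evaluate_calls(truth, truth, sizes)
  expect_equal(perfect$interval$f1, 1)
  expect_equal(perfect$base$accuracy, 1)
  none <- evaluate_calls(GenomicRanges::GRanges(), truth, sizes)
  expect_true(is.na(none$interval$precision))
  expect_equal(none$interval$recall, 0)
  expect_error(evaluate_calls(pred, GenomicRanges::GRanges(), sizes),
               "empty truth")
})
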