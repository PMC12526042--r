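# Feature-linkage filtering, open-chromatin reporting, positive share,
# discordant-enhancer detection.

test_that("correlation filtering is strict and monotone", {
  rec <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30),
                    end = c(5, 15, 25, 35), gene_id = paste0("g", 1:4),
                    correlation = c(0.2, -0.61, 0.05, 0), sample = "s1")
  kept <- filter_linkages(rec, 0.2)
  expect_equal(kept$correlation, -0.61)  # 0.2 exactly is dropped
  expect_equal(filter_linkages(rec, 0)$correlation, c(0.2, -0.61, 0.05))
  # monotone: a higher threshold keeps a subset
  set.seed(61)
  big <- data.frame(chrom = "chr1", start = 1:500, end = 2:501,
                    gene_id = "g", correlation = runif(500, -1, 1),
                    sample = "s1")
  for (t1 in c(0.1, 0.3)) {
    k1 <- filter_linkages(big, t1); k2 <- filter_linkages(big, t1 + 0.2)
    expect_true(all(rownames(k2) %in% rownames(k1)))
  }
})

test_that("linkage CSV round-trips and rejects cross-chromosome records", {
  w <- small_world(seed = 6L)
  lk <- gen_linkages(w$ann, seed = 2L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_linkages(lk, p)
  back <- read_linkages(p, w$ann$tx_set)
  expect_equal(back$gene_id, lk$gene_id)
  expect_equal(back$correlation, lk$correlation, tolerance = 1e-12)
  # a peak on the wrong chromosome is rejected on load
  bad <- lk
  bad$chrom[1] <- "chr99"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_linkages(bad, p2)
  expect_warning(got <- read_linkages(p2, w$ann$tx_set), "rejected")
  expect_equal(nrow(got), nrow(lk) - 1L)
  expect_error(validate_linkages(data.frame(chrom = "chr1", start = 0,
                                            end = 10, gene_id = "g",
                                            correlation = 1.5,
                                            sample = "s")),
               "\\[-1, 1\\]")
})

test_that("open-chromatin report recovers planted open shares", {
  cfg <- synth_config(genome_length = 1e6L, n_chroms = 1L,
                      n_genes = 40L, seed = 17L)
  ann <- gen_annotation(cfg, fraction_with_pELS = 1)
  prom <- promoter_of(ann$tx_set)
  pels <- ann$ccres[S4Vectors::mcols(ann$ccres)$class == "pELS"]
  gq <- ann$ccres  # a GQ over every element: every pair doubly flagged
  pairs <- flag_gq(build_pep_pairs(ann$tx_set, ann$ccres), gq)
  lk <- filter_linkages(gen_linkages(ann, open_fraction = 0.5, seed = 9L))
  rep1 <- open_chromatin_report(lk, prom, pels, gq, pairs)[["s1"]]
  # planted: ~50% of genes open; peak hits that gene's promoter(s) and pELS
  n_genes <- 40
  expect_true(abs(rep1$share_pels_open - 0.5) < 3 * sqrt(0.25 / n_genes))
  expect_equal(rep1$share_open_promoters_with_gq, 1)  # GQs are everywhere
  expect_equal(rep1$share_open_pels_with_gq, 1)
  expect_equal(rep1$n_gq_pep_pairs_open, rep1$n_pairs_open)
  # peaks that overlap nothing give all-zero shares
  far <- data.frame(chrom = "chr1", start = 999900, end = 999950,
                    gene_id = "g001", correlation = 0.9, sample = "sX")
  rep0 <- open_chromatin_report(far, prom, pels, gq, pairs)[["sX"]]
  expect_equal(rep0$share_promoters_open, 0)
  expect_equal(rep0$share_pels_open, 0)
  expect_equal(rep0$n_pairs_open, 0L)
  expect_error(open_chromatin_report(lk, prom, pels, gq, pairs[0, ]),
               "empty pair")
})

test_that("positive share matches the planted sign mix and is antisymmetric", {
  cfg <- synth_config(genome_length = 1e6L, n_chroms = 2L,
                      n_genes = 50L, seed = 23L)
  ann <- gen_annotation(cfg, fraction_with_pELS = 1)
  gq <- ann$ccres
  pairs <- flag_gq(build_pep_pairs(ann$tx_set, ann$ccres), gq)
  lk <- filter_linkages(gen_linkages(ann, p_negative = 0.1, seed = 31L))
  s <- positive_share(pairs, lk)
  expect_true(abs(s - 0.9) < 3 * sqrt(0.09 / nrow(lk)))
  flipped <- lk
  flipped$correlation <- -flipped$correlation
  expect_equal(positive_share(pairs, flipped), 1 - s)
  # all-positive planting gives exactly 1
  lk_pos <- filter_linkages(gen_linkages(ann, p_negative = 0, seed = 5L))
  expect_equal(positive_share(pairs, lk_pos), 1)
  expect_error(positive_share(pairs, lk[0, ]), "no linkage")
})

test_that("discordant enhancers are recovered exactly, with no false hits", {
  cfg <- synth_config(genome_length = 1e6L, n_chroms = 2L,
                      n_genes = 30L, seed = 29L)
  ann <- gen_annotation(cfg, fraction_with_pELS = 1, n_divergent_pairs = 4L)
  prom <- promoter_of(ann$tx_set)
  pels <- ann$ccres[S4Vectors::mcols(ann$ccres)$class == "pELS"]
  lk <- filter_linkages(gen_linkages(ann, plant_discordant = 4L, seed = 3L),
                        0.2)
  d <- find_discordant_enhancers(pels, lk, prom)
  expect_equal(nrow(d), 4L)
  expect_equal(d[order(d$chrom, d$pels_start), c("pels_start", "pels_end")],
               ann$divergent[order(ann$divergent$chrom,
                                   ann$divergent$pels_start),
                             c("pels_start", "pels_end")],
               ignore_attr = TRUE)
  expect_true(all(d$r_up > 0 & d$r_down < 0))
  expect_setequal(d$gene_up, ann$divergent$gene_plus)
  expect_setequal(d$gene_down, ann$divergent$gene_minus)
  # all-same-sign noise links yield zero discordant calls
  lk_pos <- filter_linkages(gen_linkages(ann, plant_discordant = 0L,
                                         p_negative = 0, seed = 7L), 0.2)
  expect_equal(nrow(find_discordant_enhancers(pels, lk_pos, prom)), 0L)
  # opposite signs to the same gene only: not discordant
  same_gene <- data.frame(chrom = ann$divergent$chrom[1],
                          start = ann$divergent$pels_start[1],
                          end = ann$divergent$pels_end[1],
                          gene_id = rep(ann$divergent$gene_plus[1], 2),
                          correlation = c(0.5, -0.5), sample = "s1")
  expect_equal(nrow(find_discordant_enhancers(pels, same_gene, prom)), 0L)
})

test_that("positive share supports per-pair and per-gene weighting", {
  cfg <- synth_config(genome_length = 1e6L, n_chroms = 1L, n_genes = 40L,
                      seed = 67L)
  ann <- gen_annotation(cfg, fraction_with_pELS = 1)
  pairs <- flag_gq(build_pep_pairs(ann$tx_set, ann$ccres), ann$ccres)
  lk <- filter_linkages(gen_linkages(ann, p_negative = 0, seed = 2L))
  # all-positive links: every weighting gives 1
  for (by in c("link", "pair", "gene")) {
    expect_equal(positive_share(pairs, lk, by = by), 1)
  }
  lk$correlation <- -lk$correlation
  for (by in c("link", "pair", "gene")) {
    expect_equal(positive_share(pairs, lk, by = by), 0)
  }
})
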