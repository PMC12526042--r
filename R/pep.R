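## Proximal enhancer-promoter (pEP) pair construction and the statistics
## computed over pair universes: Table-style count/share summaries,
## observed-versus-expected enrichment, Fisher exact tests, interval
## permutation tests, and top-fraction conservation filtering.

#' Build proximal enhancer-promoter pairs
#'
#' A pEP pair is one transcript together with one proximal enhancer-like
#' element (class `pELS`) that overlaps the transcript's promoter window
#' (`-up/+down` around the strand-aware TSS) by at least 1 bp. All such
#' transcript-by-pELS combinations are returned; a pELS may appear in many
#' pairs and a transcript may have many pairs.
#'
#' @param tx_set a [transcript_set()].
#' @param ccres `GRanges` with a `class` column; only `pELS` elements are
#'   considered.
#' @param up,down promoter geometry in bp.
#' @param chrom_sizes optional named lengths for promoter clipping.
#' @return A data frame of class `pep_pairs`, one row per (transcript,
#'   pELS) pair: `gene_id`, `transcript_id`, `chrom`, `prom_start`,
#'   `prom_end`, `enh_id`, `enh_start`, `enh_end` (coordinates 0-based
#'   half-open).
#' @export
build_pep_pairs <- function(tx_set, ccres, up = 1000L, down = 200L,
                            chrom_sizes = NULL) {
  stopifnot(inherits(tx_set, "transcript_set"))
  if (length(tx_set$transcripts) == 0L) stop("no transcripts")
  if (is.null(mcols(ccres)$class)) stop("cCREs lack a class column")
  pels <- ccres[mcols(ccres)$class == "pELS"]
  prom <- promoter_of(tx_set, up = up, down = down,
                      chrom_sizes = chrom_sizes)
  hits <- findOverlaps(prom, pels, ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  pairs <- data.frame(
    gene_id = mcols(prom)$gene_id[qi],
    transcript_id = mcols(prom)$transcript_id[qi],
    chrom = as.character(seqnames(prom))[qi],
    prom_start = start(prom)[qi] - 1L,
    prom_end = end(prom)[qi],
    enh_id = sprintf("%s:%d-%d", as.character(seqnames(pels))[si],
                     start(pels)[si] - 1L, end(pels)[si]),
    enh_start = start(pels)[si] - 1L,
    enh_end = end(pels)[si],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(pairs[c("transcript_id", "enh_id")])) {
    pairs <- pairs[!duplicated(pairs[c("transcript_id", "enh_id")]), ]
  }
  rownames(pairs) <- NULL
  class(pairs) <- c("pep_pairs", "data.frame")
  pairs
}

pair_side_gr <- function(pairs, side = c("promoter", "enhancer"),
                         flank = 0L) {
  side <- match.arg(side)
  s <- if (side == "promoter") pairs$prom_start else pairs$enh_start
  e <- if (side == "promoter") pairs$prom_end else pairs$enh_end
  gintervals(pairs$chrom, pmax(0L, s - flank), e + flank)
}

#' Flag pEP pairs for GQ presence
#'
#' Sets `gq_in_promoter` / `gq_in_enhancer` to `TRUE` when at least one GQ
#' call overlaps the pair's promoter / enhancer extended by `flank` bp on
#' each side. `flank = 0` is direct overlap; `flank = 100` reproduces the
#' DNase-site-sized window used with curated enhancer databases.
#'
#' @param pairs a [build_pep_pairs()] table.
#' @param gq_set `GRanges` of GQ calls; strand ignored.
#' @param flank non-negative bp extension of both sides.
#' @return `pairs` with the two logical flag columns.
#' @export
flag_gq <- function(pairs, gq_set, flank = 0L) {
  if (flank < 0) stop("flank must be >= 0")
  pairs$gq_in_promoter <-
    overlapsAny(pair_side_gr(pairs, "promoter", flank), gq_set,
                ignore.strand = TRUE)
  pairs$gq_in_enhancer <-
    overlapsAny(pair_side_gr(pairs, "enhancer", flank), gq_set,
                ignore.strand = TRUE)
  pairs
}

#' Pair-universe count and share statistics
#'
#' Computes the Table-style summary of a flagged pair universe: pair counts
#' and shares with a GQ in the promoter, in the enhancer, and in both;
#' gene-level analogues (a gene qualifies when at least one of its pairs
#' does); and, when `gq_set` is supplied, distinct-GQ counts (each GQ
#' counted once per statistic) in the promoters / enhancers / either side
#' of GQ pairs versus all pairs.
#'
#' @param pairs a flagged pair table (see [flag_gq()]; if flags are absent
#'   they are computed from `gq_set`).
#' @param gq_set optional `GRanges` of GQ calls, required for the
#'   distinct-GQ counts.
#' @param flank flank used when flags must be computed.
#' @return A list of class `pair_stats` with components `pairs`, `genes`
#'   and `gq`, each a data frame of counts and shares.
#' @export
pair_stats <- function(pairs, gq_set = NULL, flank = 0L) {
  if (is.null(pairs$gq_in_promoter)) {
    if (is.null(gq_set)) stop("pairs are unflagged and no gq_set given")
    pairs <- flag_gq(pairs, gq_set, flank)
  }
  n <- nrow(pairs)
  if (n == 0L) stop("empty pair universe")
  p <- pairs$gq_in_promoter; e <- pairs$gq_in_enhancer
  both <- p & e
  pair_df <- data.frame(
    statistic = c("gq_promoter", "gq_enhancer", "gq_both"),
    count = c(sum(p), sum(e), sum(both)),
    total = n,
    share = c(sum(p), sum(e), sum(both)) / n
  )
  agg <- function(flag) length(unique(pairs$gene_id[flag]))
  n_genes <- length(unique(pairs$gene_id))
  gene_df <- data.frame(
    statistic = c("gq_promoter", "gq_enhancer", "gq_both"),
    count = c(agg(p), agg(e), agg(both)),
    total = n_genes,
    share = c(agg(p), agg(e), agg(both)) / n_genes
  )
  gq_df <- NULL
  if (!is.null(gq_set)) {
    distinct_gq <- function(rows, side) {
      if (!any(rows)) return(0L)
      gr <- pair_side_gr(pairs[rows, , drop = FALSE], side, flank)
      sum(overlapsAny(gq_set, gr, ignore.strand = TRUE))
    }
    distinct_gq_either <- function(rows) {
      if (!any(rows)) return(0L)
      sub <- pairs[rows, , drop = FALSE]
      gr <- c(pair_side_gr(sub, "promoter", flank),
              pair_side_gr(sub, "enhancer", flank))
      sum(overlapsAny(gq_set, gr, ignore.strand = TRUE))
    }
    all_rows <- rep(TRUE, n)
    gq_df <- data.frame(
      statistic = c("gq_in_promoters", "gq_in_enhancers", "gq_in_pairs"),
      count = c(distinct_gq(both, "promoter"),
                distinct_gq(both, "enhancer"),
                distinct_gq_either(both)),
      total = c(distinct_gq(all_rows, "promoter"),
                distinct_gq(all_rows, "enhancer"),
                distinct_gq_either(all_rows))
    )
    gq_df$share <- ifelse(gq_df$total > 0, gq_df$count / gq_df$total, NA)
  }
  structure(list(pairs = pair_df, genes = gene_df, gq = gq_df,
                 n_pairs = n, n_genes = n_genes),
            class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("pEP pair universe: %d pairs, %d genes\n",
              x$n_pairs, x$n_genes))
  fmt <- function(df, unit) {
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-16s %8d/%d (%.2f%%) [%s]\n", df$statistic[i],
                  df$count[i], df$total[i], 100 * df$share[i], unit))
    }
  }
  fmt(x$pairs, "pairs"); fmt(x$genes, "genes")
  if (!is.null(x$gq)) fmt(x$gq, "GQ")
  invisible(x)
}

#' Reconstruct a flagged pair universe from count summaries
#'
#' Builds a minimal pair table whose flag marginals (and, optionally,
#' gene-level qualification counts) equal the given counts - useful for
#' recomputing published share and enrichment figures from their printed
#' numerator/denominator pairs through the same code paths as real data.
#'
#' @param n_pairs total pairs.
#' @param n_promoter,n_enhancer,n_both pairs with a GQ in the promoter /
#'   enhancer / both.
#' @param n_genes,n_genes_promoter,n_genes_enhancer,n_genes_both optional
#'   gene-level counts; by default each pair gets its own gene.
#' @return A flagged `pep_pairs` table (with placeholder coordinates).
#' @export
pair_universe_from_counts <- function(n_pairs, n_promoter, n_enhancer,
                                      n_both, n_genes = NULL,
                                      n_genes_promoter = NULL,
                                      n_genes_enhancer = NULL,
                                      n_genes_both = NULL) {
  stopifnot(n_both <= n_promoter, n_both <= n_enhancer,
            n_promoter <= n_pairs, n_enhancer <= n_pairs,
            n_promoter + n_enhancer - n_both <= n_pairs)
  n_po <- n_promoter - n_both          # promoter-only pairs
  n_eo <- n_enhancer - n_both          # enhancer-only pairs
  n_no <- n_pairs - n_both - n_po - n_eo
  flag_p <- rep(c(TRUE, TRUE, FALSE, FALSE), c(n_both, n_po, n_eo, n_no))
  flag_e <- rep(c(TRUE, FALSE, TRUE, FALSE), c(n_both, n_po, n_eo, n_no))
  if (is.null(n_genes)) {
    gene <- paste0("g", seq_len(n_pairs))
  } else {
    stopifnot(n_genes_both <= n_genes_promoter,
              n_genes_both <= n_genes_enhancer,
              n_genes_promoter <= n_genes, n_genes_enhancer <= n_genes)
    # one representative pair per gene fixes the gene-level flags; the
    # remaining pairs of each flag class are parked on a gene that already
    # carries those flags so gene counts are unchanged
    g_po <- n_genes_promoter - n_genes_both
    g_eo <- n_genes_enhancer - n_genes_both
    g_no <- n_genes - n_genes_both - g_po - g_eo
    stopifnot(g_no >= 0, n_genes_both <= n_both, g_po <= n_po,
              g_eo <= n_eo, g_no <= n_no)
    gene <- character(n_pairs)
    blocks <- list(
      c(n_genes_both, n_both, 1),                    # both
      c(g_po, n_po, n_genes_both + 1),               # promoter-only
      c(g_eo, n_eo, n_genes_both + g_po + 1),        # enhancer-only
      c(g_no, n_no, n_genes_both + g_po + g_eo + 1)  # neither
    )
    pos <- 1L
    for (b in blocks) {
      n_g <- b[1]; n_p <- b[2]; first_gene <- b[3]
      if (n_p == 0) next
      ids <- if (n_g > 0) {
        c(seq.int(first_gene, length.out = n_g),
          rep(first_gene, n_p - n_g))
      } else {
        rep(1L, n_p)  # parked on the first both-gene (adds no flags)
      }
      gene[seq.int(pos, length.out = n_p)] <- paste0("g", ids)
      pos <- pos + n_p
    }
  }
  pairs <- data.frame(
    gene_id = gene,
    transcript_id = paste0("t", seq_len(n_pairs)),
    chrom = "chrU",
    prom_start = 0L, prom_end = 1L,
    enh_id = paste0("e", seq_len(n_pairs)),
    enh_start = 0L, enh_end = 1L,
    gq_in_promoter = flag_p,
    gq_in_enhancer = flag_e,
    stringsAsFactors = FALSE
  )
  class(pairs) <- c("pep_pairs", "data.frame")
  pairs
}

#' Observed-versus-expected GQ pair enrichment
#'
#' The observed share is the fraction of pairs with a GQ in both sides;
#' the expected share under independence is the product of the per-side
#' flag frequencies over the same pair universe. The ratio of the two is
#' accompanied by a two-sided Fisher exact test on the 2x2
#' promoter-flag-by-enhancer-flag pair table. When a flag is constant the
#' test is degenerate: the p-value is 1 by convention and the result is
#' flagged.
#'
#' @param pairs a flagged pair table.
#' @param expected how the independence expectation is computed:
#'   `"pair"` (default) uses per-pair flag frequencies; `"element"` uses
#'   frequencies over distinct promoters and distinct enhancers, each
#'   element counted once however many pairs it joins.
#' @return A list of class `enrichment_result`: `observed_share`,
#'   `expected_share`, `ratio`, `fisher_p`, `fisher_odds`, `degenerate`.
#' @export
enrichment <- function(pairs, expected = c("pair", "element")) {
  expected <- match.arg(expected)
  if (is.null(pairs$gq_in_promoter) || is.null(pairs$gq_in_enhancer)) {
    stop("pairs must be flagged (see flag_gq)")
  }
  n <- nrow(pairs)
  if (n == 0L) stop("empty pair universe")
  p <- pairs$gq_in_promoter; e <- pairs$gq_in_enhancer
  observed <- mean(p & e)
  expected <- if (expected == "pair") {
    mean(p) * mean(e)
  } else {
    # per-distinct-element frequencies: each promoter and enhancer counted
    # once, however many pairs it joins
    prom_key <- paste(pairs$chrom, pairs$prom_start, pairs$prom_end)
    mean(p[!duplicated(prom_key)]) * mean(e[!duplicated(pairs$enh_id)])
  }
  ratio <- if (expected > 0) observed / expected else NA_real_
  tab <- matrix(c(sum(p & e), sum(p & !e), sum(!p & e), sum(!p & !e)),
                2L, 2L, byrow = TRUE)
  degenerate <- all(p) || all(!p) || all(e) || all(!e)
  if (degenerate) {
    ft <- list(odds_ratio = NA_real_, p_value = 1)
  } else {
    ft <- fisher_exact(tab)
  }
  structure(list(observed_share = observed, expected_share = expected,
                 ratio = ratio, fisher_p = ft$p_value,
                 fisher_odds = ft$odds_ratio, degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "observed %.4f vs expected %.4f: ratio %.3f (Fisher p = %.3g%s)\n",
    x$observed_share, x$expected_share, x$ratio, x$fisher_p,
    if (x$degenerate) ", degenerate margins" else ""))
  invisible(x)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided conditional exact test (hypergeometric, fixed margins): the
#' p-value sums the probabilities of all tables no more probable than the
#' observed one. The reported odds ratio is the sample cross-product
#' `ad/bc` (`Inf` when `bc = 0 < ad`, `NA` when both products are 0),
#' not the conditional MLE.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) {
    stop("need a 2x2 matrix")
  }
  if (any(table < 0)) stop("negative entry in contingency table")
  if (sum(table) == 0) stop("empty contingency table")
  a <- as.numeric(table[1, 1]); b <- as.numeric(table[1, 2])
  c <- as.numeric(table[2, 1]); d <- as.numeric(table[2, 2])
  odds <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf
    else NA_real_
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  list(odds_ratio = odds, p_value = min(1, p))
}

#' Permutation test of interval-set overlap enrichment
#'
#' The observed statistic is the number of query intervals overlapping the
#' subject set. Each permutation independently re-places every query
#' interval uniformly within its own chromosome (width preserved, no
#' exclusion zones). `fold` is observed over the mean permuted count and
#' the p-value uses the add-one estimator
#' `(1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param query,subject `GRanges` sets.
#' @param chrom_sizes named chromosome lengths.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; results are deterministic given it.
#' @return A list with `fold`, `p`, `observed` and `perm_mean`.
#' @export
permutation_enrichment <- function(query, subject, chrom_sizes,
                                   n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 1)
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  validate_intervals(query, chrom_sizes)
  chroms <- as.character(seqnames(query))
  widths <- width(query)
  if (any(widths > chrom_sizes[chroms])) {
    stop("query interval wider than its chromosome")
  }
  observed <- count_overlapping(query, subject)$n_query_hit
  set.seed(seed)
  n <- length(query)
  max_start <- rep(chrom_sizes[chroms] - widths + 1L, n_perm)
  starts <- 1L + floor(runif(n * n_perm) * max_start)
  starts <- pmin(starts, max_start)  # guard against runif returning 1
  perm_gr <- GRanges(rep(chroms, n_perm),
                     IRanges(starts, width = rep(widths, n_perm)))
  hit <- overlapsAny(perm_gr, subject, ignore.strand = TRUE)
  perm_counts <- tabulate(rep(seq_len(n_perm), each = n)[hit], n_perm)
  perm_mean <- mean(perm_counts)
  list(fold = if (perm_mean > 0) observed / perm_mean else NA_real_,
       p = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
       observed = observed, perm_mean = perm_mean)
}

#' Top fraction of scored elements
#'
#' Returns the `frac` highest-scoring elements (`k = round(frac * n)`,
#' banker's rounding), sorting by score descending with ties broken by
#' (chrom, start) ascending - deterministic for any input order.
#'
#' @param elements a `GRanges` with a `score` column.
#' @param frac fraction in (0, 1].
#' @return The subset `GRanges`, in selection order.
#' @export
top_fraction <- function(elements, frac = 0.05) {
  stopifnot(frac > 0, frac <= 1)
  score <- mcols(elements)$score
  if (is.null(score) || anyNA(score)) {
    stop("all elements must carry a non-missing score")
  }
  k <- round(frac * length(elements))
  ord <- order(-score, as.character(seqnames(elements)), start(elements))
  elements[head(ord, k)]
}
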