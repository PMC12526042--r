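## Multiome-style feature-linkage analysis: correlation filtering, open
## chromatin mapping of promoters and pELS, GQ pEP pairs in open chromatin,
## positive-correlation share, and discordant-enhancer detection.

#' Read and write feature-linkage tables
#'
#' The canonical linkage dialect is a CSV with columns `chrom`, `start`,
#' `end` (0-based half-open ATAC peak coordinates), `gene_id`,
#' `correlation` (signed, in `[-1, 1]`) and `sample`. Vendor linkage
#' exports can be flattened to this shape by keeping one row per
#' peak-gene link. When a transcript annotation is supplied, records whose
#' peak lies on a different chromosome than their gene are rejected.
#'
#' @param path CSV path.
#' @param tx_set optional [transcript_set()] used to enforce that peak and
#'   gene share a chromosome.
#' @return A data frame of linkage records.
#' @export
read_linkages <- function(path, tx_set = NULL) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "correlation", "sample")
  if (!all(need %in% names(rec))) {
    stop("linkage CSV must have columns: ", paste(need, collapse = ", "))
  }
  validate_linkages(rec, tx_set)
}

#' @rdname read_linkages
#' @param records a linkage data frame.
#' @export
write_linkages <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_linkages
#' @export
validate_linkages <- function(records, tx_set = NULL) {
  if (any(abs(records$correlation) > 1)) {
    stop("correlations must lie in [-1, 1]")
  }
  if (any(records$start < 0 | records$start >= records$end)) {
    stop("invalid peak interval in linkage records")
  }
  if (!is.null(tx_set)) {
    tx <- tx_set$transcripts
    gene_chrom <- tapply(as.character(seqnames(tx)), mcols(tx)$gene_id,
                         function(x) x[1])
    known <- records$gene_id %in% names(gene_chrom)
    bad <- known & records$chrom != gene_chrom[records$gene_id]
    if (any(bad)) {
      records <- records[!bad, , drop = FALSE]
      warning(sum(bad), " record(s) with peak and gene on different ",
              "chromosomes rejected")
    }
  }
  records
}

linkage_peaks_gr <- function(records) {
  gr <- gintervals(records$chrom, records$start, records$end)
  mcols(gr)$gene_id <- records$gene_id
  mcols(gr)$correlation <- records$correlation
  mcols(gr)$sample <- records$sample
  gr
}

#' Filter linkage records by absolute correlation
#'
#' Keeps records with `|correlation|` strictly greater than the threshold
#' ("over 0.2" semantics: a record at exactly the threshold is dropped).
#'
#' @param records linkage data frame.
#' @param min_abs_r threshold in `[0, 1]`.
#' @return The retained records.
#' @export
filter_linkages <- function(records, min_abs_r = 0.2) {
  stopifnot(min_abs_r >= 0, min_abs_r <= 1)
  records[abs(records$correlation) > min_abs_r, , drop = FALSE]
}

#' Open-chromatin report for promoters, pELS and GQ pEP pairs
#'
#' An element is "open" in a sample iff at least one retained ATAC peak
#' overlaps it. Reports, per sample: open promoter and pELS counts and
#' shares, the GQ sub-shares among open elements, the number of pEP pairs
#' open on both sides, the number of those that are GQ pEP pairs, and the
#' observed-versus-expected GQ enrichment over the open-pair universe.
#'
#' @param records filtered linkage records (see [filter_linkages()]).
#' @param promoters promoter `GRanges` (e.g. [promoter_of()] on the
#'   annotation).
#' @param pels `GRanges` of proximal enhancer-like elements.
#' @param gq_set `GRanges` of GQ calls.
#' @param pairs a flagged pair table from [build_pep_pairs()] +
#'   [flag_gq()].
#' @return A list of class `open_chromatin_report`, one entry per sample.
#' @export
open_chromatin_report <- function(records, promoters, pels, gq_set, pairs) {
  if (nrow(pairs) == 0L) stop("empty pair universe")
  if (is.null(pairs$gq_in_promoter)) stop("pairs must be flagged")
  samples <- sort(unique(records$sample))
  prom_gq <- overlapsAny(promoters, gq_set, ignore.strand = TRUE)
  pels_gq <- overlapsAny(pels, gq_set, ignore.strand = TRUE)
  prom_pair_gr <- pair_side_gr(pairs, "promoter")
  enh_pair_gr <- pair_side_gr(pairs, "enhancer")
  out <- lapply(samples, function(sm) {
    peaks <- linkage_peaks_gr(records[records$sample == sm, , drop = FALSE])
    prom_open <- overlapsAny(promoters, peaks, ignore.strand = TRUE)
    pels_open <- overlapsAny(pels, peaks, ignore.strand = TRUE)
    pair_open <- overlapsAny(prom_pair_gr, peaks, ignore.strand = TRUE) &
      overlapsAny(enh_pair_gr, peaks, ignore.strand = TRUE)
    open_pairs <- pairs[pair_open, , drop = FALSE]
    enr <- if (nrow(open_pairs) > 0) enrichment(open_pairs) else NULL
    list(
      sample = sm,
      n_promoters = length(promoters),
      n_promoters_open = sum(prom_open),
      share_promoters_open = mean(prom_open),
      n_open_promoters_with_gq = sum(prom_open & prom_gq),
      share_open_promoters_with_gq =
        if (any(prom_open)) mean(prom_gq[prom_open]) else NA_real_,
      n_pels = length(pels),
      n_pels_open = sum(pels_open),
      share_pels_open = mean(pels_open),
      n_open_pels_with_gq = sum(pels_open & pels_gq),
      share_open_pels_with_gq =
        if (any(pels_open)) mean(pels_gq[pels_open]) else NA_real_,
      n_pairs_open = nrow(open_pairs),
      n_gq_pep_pairs_open =
        sum(open_pairs$gq_in_promoter & open_pairs$gq_in_enhancer),
      enrichment = enr
    )
  })
  names(out) <- samples
  class(out) <- "open_chromatin_report"
  out
}

# links between retained records and pairs: gene identity must match and
# the peak must overlap the pair's promoter or enhancer
pair_record_links <- function(pairs, records) {
  peaks <- linkage_peaks_gr(records)
  prom_gr <- pair_side_gr(pairs, "promoter")
  enh_gr <- pair_side_gr(pairs, "enhancer")
  h1 <- findOverlaps(prom_gr, peaks, ignore.strand = TRUE)
  h2 <- findOverlaps(enh_gr, peaks, ignore.strand = TRUE)
  pi <- c(queryHits(h1), queryHits(h2))
  ri <- c(subjectHits(h1), subjectHits(h2))
  keep <- pairs$gene_id[pi] == records$gene_id[ri]
  links <- unique(data.frame(pair = pi[keep], record = ri[keep]))
  links
}

#' Share of positively correlated GQ pEP pair links
#'
#' Among (pair, record) links touching GQ pEP pairs - the record's gene
#' matches the pair's gene and its peak overlaps the pair's promoter or
#' enhancer, and the pair has a GQ on both sides - the share with positive
#' correlation.
#'
#' Alternative weightings: `by = "pair"` counts each GQ pEP pair once
#' (positive iff the mean correlation of its links is positive) and
#' `by = "gene"` counts each gene once, aggregating its pairs' links the
#' same way. The default counts every (pair, record) link.
#'
#' @param pairs_open a flagged pair table (typically the open-pair
#'   universe).
#' @param records filtered linkage records.
#' @param by weighting unit: `"link"` (default), `"pair"` or `"gene"`.
#' @return The share in `[0, 1]`.
#' @export
positive_share <- function(pairs_open, records,
                           by = c("link", "pair", "gene")) {
  by <- match.arg(by)
  if (is.null(pairs_open$gq_in_promoter)) stop("pairs must be flagged")
  gq_rows <- which(pairs_open$gq_in_promoter & pairs_open$gq_in_enhancer)
  links <- pair_record_links(pairs_open, records)
  links <- links[links$pair %in% gq_rows, , drop = FALSE]
  if (nrow(links) == 0L) {
    stop("no linkage records touch a GQ pEP pair")
  }
  r <- records$correlation[links$record]
  switch(by,
    link = mean(r > 0),
    pair = mean(tapply(r, links$pair, mean) > 0),
    gene = mean(tapply(r, pairs_open$gene_id[links$pair], mean) > 0)
  )
}

#' Detect discordant enhancers
#'
#' A discordant enhancer is a pELS, overlapped by at least one retained
#' ATAC peak, whose peak(s) carry correlations of opposite sign to two
#' distinct genes, where the pELS either lies between the two genes'
#' promoter regions or overlaps both - the geometry of a candidate
#' tissue-specific switch. When several genes qualify on a side, the gene
#' whose promoter is nearest the pELS is reported. Results are ordered by
#' coordinate.
#'
#' @param pels `GRanges` of proximal enhancer-like elements.
#' @param records filtered linkage records.
#' @param promoters promoter `GRanges` carrying a `gene_id` column.
#' @return A data frame: `chrom`, `pels_start`, `pels_end` (0-based
#'   half-open), `gene_up`, `r_up`, `gene_down`, `r_down`.
#' @export
find_discordant_enhancers <- function(pels, records, promoters) {
  if (is.null(mcols(promoters)$gene_id)) {
    stop("promoters must carry a gene_id column")
  }
  peaks <- linkage_peaks_gr(records)
  # per-gene promoter region: the reduced span of that gene's promoters
  gene_ids <- unique(mcols(promoters)$gene_id)
  gene_prom <- lapply(gene_ids, function(g) {
    range(promoters[mcols(promoters)$gene_id == g], ignore.strand = TRUE)
  })
  gene_prom <- unlist(GRangesList(gene_prom), use.names = FALSE)
  names(gene_prom) <- gene_ids
  hits <- findOverlaps(pels, peaks, ignore.strand = TRUE)
  rows <- list()
  for (i in unique(queryHits(hits))) {
    ri <- subjectHits(hits)[queryHits(hits) == i]
    el <- pels[i]
    cand <- data.frame(gene = records$gene_id[ri],
                       r = records$correlation[ri])
    cand <- cand[cand$gene %in% gene_ids, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # geometry: the pELS must overlap the gene's promoter region or be
    # strictly to one side of it (no overlap required for "between")
    g_ok <- vapply(unique(cand$gene), function(g) {
      as.character(seqnames(gene_prom[g])) == as.character(seqnames(el))
    }, logical(1))
    cand <- cand[cand$gene %in% names(g_ok)[g_ok], , drop = FALSE]
    pos <- cand[cand$r > 0, , drop = FALSE]
    neg <- cand[cand$r < 0, , drop = FALSE]
    if (nrow(pos) == 0L || nrow(neg) == 0L) next
    dist_to <- function(g) {
      gp <- gene_prom[g]
      max(0L, start(gp) - end(el), start(el) - end(gp))
    }
    pick <- function(side) {
      d <- vapply(side$gene, dist_to, numeric(1))
      best <- order(d, -abs(side$r))[1]
      side[best, , drop = FALSE]
    }
    up <- pick(pos); down <- pick(neg)
    if (up$gene == down$gene) next
    # the pair must sandwich or cover the pELS: each promoter region
    # either overlaps the pELS or the pELS lies between the two regions
    gp_u <- gene_prom[up$gene]; gp_d <- gene_prom[down$gene]
    ov_u <- gi_overlaps(gp_u, el); ov_d <- gi_overlaps(gp_d, el)
    between <- (end(gp_u) < start(el) && end(el) < start(gp_d)) ||
      (end(gp_d) < start(el) && end(el) < start(gp_u))
    if (!((ov_u && ov_d) || between)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(el)),
      pels_start = start(el) - 1L, pels_end = end(el),
      gene_up = up$gene, r_up = up$r,
      gene_down = down$gene, r_down = down$r,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), pels_start = integer(),
                      pels_end = integer(), gene_up = character(),
                      r_up = numeric(), gene_down = character(),
                      r_down = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pels_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
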