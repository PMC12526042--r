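## Strand-aware promoter construction, genomic-region classification of GQ
## sets, pairwise method-overlap matrices, and confidence-level-stratified
## concordance.

REGION_LABELS <- c("promoter", "five_prime_utr", "three_prime_utr",
                   "exon", "intron", "intergenic")

#' Strand-aware promoter windows
#'
#' The promoter of a transcript covers `up` bp upstream and `down` bp
#' downstream of its strand-aware TSS (defaults 1000/200), mirrored on the
#' minus strand, and clipped at chromosome bounds when sizes are supplied.
#'
#' @param tx either a [transcript_set()] or a stranded `GRanges` of
#'   transcript spans.
#' @param up,down bp upstream/downstream of the TSS.
#' @param chrom_sizes optional named lengths for boundary clipping.
#' @return A `GRanges` of promoter windows, parallel to the transcripts,
#'   with their metadata columns carried over. Width is `up + down`
#'   whenever unclipped.
#' @examples
#' tx <- gintervals("chr1", 10000, 15000, strand = "+")
#' gr_to_bed_df(promoter_of(tx))  # [9000, 10200)
#' @export
promoter_of <- function(tx, up = 1000L, down = 200L, chrom_sizes = NULL) {
  gr <- if (inherits(tx, "transcript_set")) tx$transcripts else tx
  if (any(!as.character(strand(gr)) %in% c("+", "-"))) {
    stop("promoter_of needs stranded transcripts")
  }
  prom <- suppressWarnings(promoters(gr, upstream = up, downstream = down))
  ns <- pmax(1L, start(prom))
  ne <- end(prom)
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- check_chrom_sizes(chrom_sizes)
    ne <- pmin(ne, chrom_sizes[as.character(seqnames(prom))])
  }
  if (any(ns > ne)) {
    stop("promoter clipped to an empty interval (TSS outside chromosome?)")
  }
  ranges(prom) <- IRanges(unname(ns), unname(ne))
  prom
}

#' Classify intervals by genomic region
#'
#' Assigns each interval the highest-precedence region it overlaps by at
#' least 1 bp: promoter > 5'UTR > 3'UTR > exon > intron > intergenic.
#' An intron is a position within a transcript span that is none of the
#' higher categories; intergenic overlaps nothing. UTR labels require UTR
#' tracks in the annotation (otherwise those bases classify as exon).
#' Strand is ignored.
#'
#' @param intervals `GRanges` to classify.
#' @param tx_set a [transcript_set()].
#' @param up,down promoter geometry passed to [promoter_of()].
#' @return A character vector of region labels, parallel to `intervals`.
#' @export
classify_region <- function(intervals, tx_set, up = 1000L, down = 200L) {
  stopifnot(inherits(tx_set, "transcript_set"))
  cats <- list(
    promoter = promoter_of(tx_set, up = up, down = down),
    five_prime_utr = tx_set$utr5,
    three_prime_utr = tx_set$utr3,
    exon = tx_set$exons,
    intron = tx_set$transcripts
  )
  label <- rep("intergenic", length(intervals))
  undecided <- rep(TRUE, length(intervals))
  for (nm in names(cats)) {
    if (!length(cats[[nm]])) next
    hit <- undecided & overlapsAny(intervals, cats[[nm]], ignore.strand = TRUE)
    label[hit] <- nm
    undecided <- undecided & !hit
  }
  label
}

#' Region distribution of a GQ set
#'
#' Each interval is counted once under its [classify_region()] label;
#' fractions sum to 1.
#'
#' @inheritParams classify_region
#' @param gq_set non-empty `GRanges`.
#' @return Named numeric vector of fractions over all six region labels.
#' @export
region_distribution <- function(gq_set, tx_set, up = 1000L, down = 200L) {
  if (length(gq_set) == 0L) stop("empty GQ set: distribution undefined")
  lab <- factor(classify_region(gq_set, tx_set, up, down),
                levels = REGION_LABELS)
  tab <- table(lab)
  setNames(as.numeric(tab) / length(gq_set), REGION_LABELS)
}

#' Pairwise method-overlap matrix
#'
#' Entry (i, j) is the fraction of set i's intervals with at least 1 bp
#' overlap in set j (row-normalized, asymmetric); the diagonal is 1.
#' Rows for empty sets are `NA`.
#'
#' @param method_sets named list of two or more `GRanges` call sets.
#' @return A numeric matrix with the sets' names as dimnames.
#' @export
overlap_matrix <- function(method_sets) {
  if (length(method_sets) < 2L || is.null(names(method_sets))) {
    stop("need a named list of at least two call sets")
  }
  n <- length(method_sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(method_sets),
                                              names(method_sets)))
  for (i in seq_len(n)) {
    if (length(method_sets[[i]]) == 0L) next
    for (j in seq_len(n)) {
      m[i, j] <- count_overlapping(method_sets[[i]],
                                   method_sets[[j]])$fraction
    }
  }
  m
}

#' Level-stratified concordance with a predicted set
#'
#' For each confidence level and region label, the fraction of calls at
#' that level classified in that region that overlap at least one
#' predicted interval. Empty strata are `NA`.
#'
#' @param pred `GRanges` of predictions.
#' @param leveled_calls `GRanges` with an integer `level` column.
#' @param tx_set a [transcript_set()] used for region classification.
#' @param up,down promoter geometry.
#' @return A data frame with `level`, `region`, `n` and `fraction`.
#' @export
level_stratified_overlap <- function(pred, leveled_calls, tx_set,
                                     up = 1000L, down = 200L) {
  if (is.null(mcols(leveled_calls)$level)) {
    stop("leveled_calls lack a level column")
  }
  lab <- classify_region(leveled_calls, tx_set, up, down)
  hit <- overlapsAny(leveled_calls, pred, ignore.strand = TRUE)
  levels_seen <- sort(unique(mcols(leveled_calls)$level))
  grid <- expand.grid(level = levels_seen, region = REGION_LABELS,
                      stringsAsFactors = FALSE)
  grid$n <- NA_integer_; grid$fraction <- NA_real_
  for (k in seq_len(nrow(grid))) {
    sel <- mcols(leveled_calls)$level == grid$level[k] &
      lab == grid$region[k]
    grid$n[k] <- sum(sel)
    if (any(sel)) grid$fraction[k] <- mean(hit[sel])
  }
  grid
}
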