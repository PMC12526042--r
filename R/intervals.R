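## Interval algebra on GRanges with BED-style (0-based half-open) coordinates
## at every user-facing boundary.

#' Construct genomic intervals from BED-style coordinates
#'
#' Builds a [GenomicRanges::GRanges] from 0-based half-open coordinates, the
#' convention used by BED files and by every coordinate table this package
#' reads or writes. Internally intervals are stored 1-based closed (the
#' GRanges convention); use [gr_to_bed_df()] to get BED-style coordinates
#' back.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, so a 1-bp interval at
#'   the first base of a chromosome is `start = 0, end = 1`. Empty intervals
#'   (`start >= end`) and negative starts are rejected.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @param name,score optional per-interval metadata.
#' @param chrom_sizes optional named vector of chromosome lengths (bp). When
#'   given, every interval is validated to lie within its chromosome and the
#'   lengths are attached as `seqlengths`.
#'
#' @return A `GRanges` object.
#' @examples
#' gintervals("chr1", 0, 10)                  # first ten bases of chr1
#' gintervals("chr1", c(0, 9), c(10, 20), strand = c("+", "-"))
#' @export
gintervals <- function(chrom, start, end, strand = "*", name = NULL,
                       score = NULL, chrom_sizes = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) == 0L) {
    gr <- GRanges()
    if (!is.null(name)) mcols(gr)$name <- character(0)
    if (!is.null(score)) mcols(gr)$score <- numeric(0)
    return(gr)
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be non-missing numbers")
  }
  if (any(start < 0)) {
    stop("interval start must be >= 0 (0-based half-open coordinates)")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("empty or inverted interval rejected: start %d >= end %d",
                 start[bad], end[bad]))
  }
  gr <- GRanges(as.character(chrom), IRanges(start + 1L, end), strand = strand)
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  if (!is.null(chrom_sizes)) {
    validate_intervals(gr, chrom_sizes)
    seqlengths(gr) <- chrom_sizes[seqlevels(gr)]
  }
  gr
}

#' Convert a GRanges to a BED-style data frame
#'
#' @param gr a `GRanges`.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, plus any metadata columns of `gr`.
#' @examples
#' gr_to_bed_df(gintervals("chr1", 0, 10))
#' @export
gr_to_bed_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    strand = as.character(strand(gr)),
    stringsAsFactors = FALSE
  )
  md <- as.data.frame(mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  rownames(df) <- NULL
  df
}

#' @rdname gr_to_bed_df
#' @param df a data frame with `chrom`, `start`, `end` and optionally
#'   `strand` plus metadata columns, 0-based half-open.
#' @export
bed_df_to_gr <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  gr <- gintervals(df$chrom, df$start, df$end, strand = strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  for (col in extra) mcols(gr)[[col]] <- df[[col]]
  gr
}

#' Validate intervals against chromosome sizes
#'
#' Checks that every interval's chromosome is present in `chrom_sizes` and
#' that no interval extends past the chromosome end.
#'
#' @param gr a `GRanges`.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), all
#'   positive.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_intervals <- function(gr, chrom_sizes) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  chroms <- as.character(seqnames(gr))
  missing <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(missing)) {
    stop("chromosome(s) absent from chrom_sizes: ",
         paste(missing, collapse = ", "))
  }
  over <- end(gr) > chrom_sizes[chroms]
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("interval %s:%d-%d extends past chromosome end (%d bp)",
                 chroms[i], start(gr)[i] - 1L, end(gr)[i],
                 chrom_sizes[[chroms[i]]]))
  }
  invisible(TRUE)
}

check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector of chromosome lengths")
  }
  if (any(chrom_sizes <= 0)) stop("all chromosome lengths must be positive")
  chrom_sizes
}

#' Pairwise interval overlap
#'
#' `TRUE` iff the two intervals share at least one base: same chromosome and
#' `max(starts) < min(ends)`. Strand is ignored; half-open adjacency does not
#' count as overlap.
#'
#' @param a,b single-interval `GRanges` (or parallel `GRanges` of equal
#'   length, compared element-wise).
#' @return Logical vector.
#' @examples
#' gi_overlaps(gintervals("chr1", 0, 10), gintervals("chr1", 9, 20))  # TRUE
#' gi_overlaps(gintervals("chr1", 0, 10), gintervals("chr1", 10, 20)) # FALSE
#' @export
gi_overlaps <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    pmax(start(a), start(b)) <= pmin(end(a), end(b))
}

#' Merge intervals closer than a gap
#'
#' Per chromosome, joins any two intervals whose gap is at most `max_gap`
#' bases (0 = touching or overlapping) and returns the sorted union. Strand
#' is ignored and dropped.
#'
#' @param gr a `GRanges`.
#' @param max_gap non-negative integer gap (bp) up to which intervals are
#'   bridged.
#' @return A sorted, strand-free `GRanges` covering exactly the union of the
#'   inputs plus bridged gaps.
#' @examples
#' gi_merge(gintervals("chr1", c(0, 10), c(10, 20)))        # one interval
#' gi_merge(gintervals("chr1", c(0, 15), c(10, 20)), max_gap = 5)
#' @export
gi_merge <- function(gr, max_gap = 0L) {
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single non-negative integer")
  }
  gr <- granges(gr)
  strand(gr) <- "*"
  # reduce() joins ranges separated by a gap < min.gapwidth
  reduce(gr, min.gapwidth = max_gap + 1L)
}

#' Count query intervals hit by a subject set
#'
#' Asymmetric overlap share: how many (and what fraction of) query intervals
#' have at least 1 bp overlap with any subject interval.
#'
#' @param query,subject `GRanges` sets; strand is ignored.
#' @return A list with `n_query_hit` and `fraction`.
#' @examples
#' q <- gintervals("chr1", c(0, 20), c(10, 30))
#' s <- gintervals("chr1", 5, 6)
#' count_overlapping(q, s)  # 1 of 2
#' @export
count_overlapping <- function(query, subject) {
  if (length(query) == 0L) {
    stop("empty query set: overlap fraction is undefined")
  }
  hit <- overlapsAny(query, subject, ignore.strand = TRUE)
  list(n_query_hit = sum(hit), fraction = sum(hit) / length(query))
}
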