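## Canonical GQ motif scanning and desk-scale genome calling.
##
## The canonical motif is (G3-5 N1-7)4: four runs of 3-5 guanines separated
## by three loops of 1-7 arbitrary bases, width 15..41 bp. The scanner
## policy is deterministic: positions are visited left to right; at the
## first position admitting a match, the shortest match starting there is
## taken (ties broken by minimal run lengths, then minimal loop lengths,
## left to right) and scanning resumes after its end, so reported matches
## are non-overlapping per strand.

MOTIF_MIN_WIDTH <- 15L
MOTIF_MAX_WIDTH <- 41L

# consecutive-G count starting at each position (N never counts as G)
g_run_count <- function(ch) {
  g <- ch == "G"
  r <- rle(g)
  counts <- integer(length(ch))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    counts[starts[i]:ends[i]] <- r$lengths[i]:1L
  }
  counts
}

# All feasible (r1..r4, l1..l3) combos at 1-based position p, as a matrix.
# gcount[p] >= r means positions p..p+r-1 are all G; loops are unconstrained.
motif_combos_at <- function(gcount, p, L) {
  out <- vector("list", 32L); n_out <- 0L
  for (r1 in 3:5) {
    if (gcount[p] < r1) break
    q1 <- p + r1
    for (l1 in 1:7) {
      p2 <- q1 + l1
      if (p2 > L) break
      for (r2 in 3:5) {
        if (gcount[p2] < r2) break
        q2 <- p2 + r2
        for (l2 in 1:7) {
          p3 <- q2 + l2
          if (p3 > L) break
          for (r3 in 3:5) {
            if (gcount[p3] < r3) break
            q3 <- p3 + r3
            for (l3 in 1:7) {
              p4 <- q3 + l3
              if (p4 > L) break
              for (r4 in 3:5) {
                if (gcount[p4] < r4) break
                if (p4 + r4 - 1L > L) break
                n_out <- n_out + 1L
                out[[n_out]] <- c(r1, r2, r3, r4, l1, l2, l3)
              }
            }
          }
        }
      }
    }
  }
  if (n_out == 0L) return(NULL)
  do.call(rbind, out[seq_len(n_out)])
}

# Shortest match starting exactly at p (ties: minimal runs then loops,
# left to right), or NULL.
best_motif_at <- function(gcount, p, L) {
  combos <- motif_combos_at(gcount, p, L)
  if (is.null(combos)) return(NULL)
  widths <- rowSums(combos)
  best <- which(widths == min(widths))
  if (length(best) > 1L) {
    ord <- do.call(order, as.data.frame(combos[best, , drop = FALSE]))
    best <- best[ord[1L]]
  }
  list(runs = combos[best, 1:4], loops = combos[best, 5:7],
       width = widths[best])
}

# Non-overlapping left-to-right scan of one strand; ch is a character
# vector over {A,C,G,T,N}. Returns a data.frame of 1-based matches.
scan_strand <- function(ch) {
  L <- length(ch)
  gcount <- g_run_count(ch)
  cand <- which(gcount >= 3L)
  cand <- cand[cand + MOTIF_MIN_WIDTH - 1L <= L]
  starts <- integer(0); widths <- integer(0)
  runs <- list(); loops <- list()
  resume <- 1L
  for (p in cand) {
    if (p < resume) next
    m <- best_motif_at(gcount, p, L)
    if (is.null(m)) next
    starts <- c(starts, p); widths <- c(widths, m$width)
    runs[[length(runs) + 1L]] <- m$runs
    loops[[length(loops) + 1L]] <- m$loops
    resume <- p + m$width
  }
  data.frame(start = starts, end = starts + widths - 1L,
             runs = vapply(runs, paste, "", collapse = ","),
             loops = vapply(loops, paste, "", collapse = ","))
}

#' Find canonical GQ motifs in a DNA sequence
#'
#' Scans for the canonical quadruplex-forming grammar: four G-runs of 3-5
#' guanines separated by three loops of 1-7 arbitrary bases (width 15-41
#' bp). `N` may appear in loops but never counts towards a G-run. The
#' reverse strand is scanned on the reverse complement and coordinates are
#' mapped back. See the scanner policy note in the package vignette: per
#' strand, matches are non-overlapping, each the shortest match at its
#' start position.
#'
#' @param sequence a single DNA string (character or `DNAString`) over
#'   `{A,C,G,T,N}`; lower case is accepted.
#' @param both_strands scan the reverse strand too?
#' @param chrom chromosome name used in the returned ranges.
#' @return A stranded `GRanges` (1-based closed internally, as all package
#'   objects) with metadata columns `runs` and `loops` (comma-separated
#'   lengths) and `width_bp`.
#' @examples
#' find_canonical_motifs("GGGAGGGAGGGAGGG", both_strands = FALSE)
#' find_canonical_motifs("CCCTCCCTCCCTCCC")  # minus-strand match only
#' @export
find_canonical_motifs <- function(sequence, both_strands = TRUE,
                                  chrom = "seq") {
  s <- toupper(as.character(sequence))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N")))) {
    stop("non-DNA character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  L <- length(ch)
  fwd <- scan_strand(ch)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (both_strands && L >= MOTIF_MIN_WIDTH) {
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
    rh <- scan_strand(unname(rc))
    if (nrow(rh)) {
      rh <- data.frame(start = L - rh$end + 1L, end = L - rh$start + 1L,
                       runs = rh$runs, loops = rh$loops, strand = "-")
      hits <- rbind(hits, rh)
    }
  }
  if (!nrow(hits)) {
    return(GRanges(runs = character(0), loops = character(0),
                   width_bp = integer(0)))
  }
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  GRanges(rep(chrom, nrow(hits)), IRanges(hits$start, hits$end),
          strand = hits$strand, runs = hits$runs, loops = hits$loops,
          width_bp = hits$end - hits$start + 1L)
}

#' Parameters for genome-wide GQ calling
#'
#' Defaults follow the center-context design: score 512-bp windows, keep
#' only the central 128 bp of each scored window (so every retained base
#' has at least 192 bp of context on each side), advance placements by a
#' 192-bp stride, call at a decision threshold of 0.25, and keep calls of
#' at least 15 bp. `stride = 192` with 128-bp centers leaves 64-bp gaps
#' between consecutive centers; pass `stride = 128` for gap-free center
#' coverage.
#'
#' @param window_size scored window width (bp).
#' @param center_width width of the retained central segment (bp).
#' @param stride placement step (bp).
#' @param threshold decision threshold in (0, 1).
#' @param min_len minimum call width retained (bp).
#' @param merge_gap gap (bp) up to which emitted centers are merged.
#' @return A list of class `call_params`.
#' @export
call_params <- function(window_size = 512L, center_width = 128L,
                        stride = 192L, threshold = 0.25, min_len = 15L,
                        merge_gap = 0L) {
  context <- (window_size - center_width) / 2
  stopifnot(threshold > 0, threshold < 1, min_len >= 1, merge_gap >= 0,
            stride >= 1, center_width >= 1, context >= 0,
            context == floor(context))
  structure(list(window_size = as.integer(window_size),
                 center_width = as.integer(center_width),
                 context = as.integer(context),
                 stride = as.integer(stride),
                 threshold = threshold,
                 min_len = as.integer(min_len),
                 merge_gap = as.integer(merge_gap)),
            class = "call_params")
}

#' Motif-coverage score of a 512-bp window
#'
#' The package's default window scorer, honoring the pluggable contract
#' (512-bp sequence in, probability-like score in `[0, 1]` out): the number
#' of central-128-bp bases covered by any canonical motif (either strand),
#' divided by 15 (the minimal motif width) and capped at 1. Monotone in
#' central motif coverage; a window whose center is devoid of motifs scores
#' 0 and one containing a full centered motif scores 1.
#'
#' @param sequence a 512-character DNA string.
#' @param params a [call_params()] (supplies window and center geometry).
#' @return A score in `[0, 1]`.
#' @export
default_window_score <- function(sequence, params = call_params()) {
  s <- toupper(as.character(sequence))
  if (nchar(s) != params$window_size) {
    stop("scorer expects a ", params$window_size, "-bp window, got ",
         nchar(s), " bp")
  }
  motifs <- find_canonical_motifs(s, both_strands = TRUE)
  center <- IRanges(params$context + 1L,
                    params$context + params$center_width)
  if (!length(motifs)) return(0)
  cov <- reduce(ranges(motifs))
  covered <- sum(width(intersect(cov, center)))
  min(1, covered / MOTIF_MIN_WIDTH)
}

#' Call GQ intervals genome-wide
#'
#' Places `window_size`-bp scoring windows at starts `0, stride, 2*stride,
#' ...` (while a full window fits; chromosomes shorter than one window are
#' skipped with a warning, and no padding is used so every retained base
#' keeps its full context). Windows scoring at or above the threshold emit
#' their central `center_width` interval; emitted centers are merged with
#' `merge_gap`; within each merged region the motif-supported sub-intervals
#' are retained where canonical motifs are present (with the motif strand),
#' otherwise the region itself is kept unstranded; calls narrower than
#' `min_len` are dropped.
#'
#' With the default `scorer = NULL` the motif-coverage score
#' ([default_window_score()]) is computed from a single whole-chromosome
#' motif scan, which is equivalent to scoring each window in isolation
#' except for motifs truncated at window edges (which cannot affect the
#' 128-bp center, buffered by 192 bp of context). Pass a function
#' `function(sequence) -> [0,1]` to use a custom scorer, or use
#' `score_track` to import per-window scores computed elsewhere.
#'
#' @param genome named `DNAStringSet` (or a path read via [read_fasta()]).
#' @param params a [call_params()].
#' @param scorer optional function from a window sequence to a score.
#' @param score_track optional `GRanges` of pre-computed window scores
#'   (`score` column; one range per window placement) used instead of any
#'   scorer.
#' @return A `GRanges` of calls with `score` (maximum supporting window
#'   score) metadata.
#' @export
call_genome <- function(genome, params = call_params(), scorer = NULL,
                        score_track = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  stopifnot(is(genome, "DNAStringSet"))
  w <- params$window_size
  out <- list()
  for (chrom in names(genome)) {
    L <- width(genome)[match(chrom, names(genome))]
    if (L < w) {
      warning("chromosome ", chrom, " shorter than one window (", L,
              " < ", w, " bp); skipped")
      next
    }
    seq_c <- as.character(genome[[chrom]])
    starts0 <- seq.int(0L, L - w, by = params$stride)  # 0-based placements
    motifs <- find_canonical_motifs(seq_c, both_strands = TRUE,
                                    chrom = chrom)
    if (!is.null(score_track)) {
      st <- score_track[seqnames(score_track) == chrom]
      idx <- match(start(st) - 1L, starts0)
      scores <- rep(0, length(starts0))
      scores[idx[!is.na(idx)]] <- mcols(st)$score[!is.na(idx)]
    } else if (!is.null(scorer)) {
      scores <- vapply(starts0, function(s0) {
        scorer(substr(seq_c, s0 + 1L, s0 + w))
      }, numeric(1))
    } else {
      # fast path: coverage of the whole-chromosome motif scan
      cov_mask <- coverage(reduce(ranges(motifs)), width = L) > 0
      csum <- c(0, cumsum(as.integer(cov_mask)))
      c_from <- starts0 + params$context + 1L
      c_to <- c_from + params$center_width - 1L
      covered <- csum[c_to + 1L] - csum[c_from]
      scores <- pmin(1, covered / MOTIF_MIN_WIDTH)
    }
    if (any(scores < 0 | scores > 1)) {
      stop("scorer returned a value outside [0, 1]")
    }
    hit <- scores >= params$threshold
    if (!any(hit)) next
    centers <- GRanges(chrom,
                       IRanges(starts0[hit] + params$context + 1L,
                               width = params$center_width))
    mcols(centers)$score <- scores[hit]
    merged <- gi_merge(centers, max_gap = params$merge_gap)
    # retain motif support inside each merged region where available
    region_calls <- lapply(seq_along(merged), function(i) {
      reg <- merged[i]
      sup <- motifs[overlapsAny(motifs, reg, ignore.strand = TRUE)]
      calls <- if (length(sup)) {
        restrict(reduce(granges(sup)), start = start(reg), end = end(reg))
      } else {
        reg
      }
      sc <- max(mcols(centers)$score[overlapsAny(centers, reg)])
      mcols(calls)$score <- sc
      calls
    })
    out[[chrom]] <- unlist(GRangesList(region_calls), use.names = FALSE)
  }
  if (!length(out)) {
    res <- GRanges(); mcols(res)$score <- numeric(0)
    return(res)
  }
  res <- unlist(GRangesList(out), use.names = FALSE)
  res <- res[width(res) >= params$min_len]
  sort(res, ignore.strand = TRUE)
}

#' Evaluate a call set against truth intervals
#'
#' Interval-level: a predicted call is a true positive if it overlaps at
#' least one truth interval by 1 bp or more; recall is the fraction of
#' truth intervals overlapped by any call. Base-level: the per-base
#' confusion matrix over all chromosome bases. Strand is ignored in both.
#'
#' @param predicted,truth `GRanges` sets on the same chromosome universe.
#' @param chrom_sizes named lengths (needed for base-level true negatives).
#' @return A list of two data frames, `interval` (precision, recall, f1)
#'   and `base` (precision, recall, f1, accuracy). With no predictions,
#'   precision and f1 are `NA` and recall is 0.
#' @export
evaluate_calls <- function(predicted, truth, chrom_sizes) {
  if (length(truth) == 0L) stop("empty truth set: recall is undefined")
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  validate_intervals(truth, chrom_sizes)
  f1_of <- function(p, r) {
    if (is.na(p) || (p + r) == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  if (length(predicted) == 0L) {
    int_p <- NA_real_; int_r <- 0
    base_p <- NA_real_; base_r <- 0
    tn <- sum(chrom_sizes) - sum(width(gi_merge(truth)))
    base_acc <- tn / sum(chrom_sizes)
  } else {
    validate_intervals(predicted, chrom_sizes)
    int_p <- mean(overlapsAny(predicted, truth, ignore.strand = TRUE))
    int_r <- mean(overlapsAny(truth, predicted, ignore.strand = TRUE))
    pm <- gi_merge(predicted); tm <- gi_merge(truth)
    tp <- sum(width(suppressWarnings(intersect(pm, tm))))
    fp <- sum(width(pm)) - tp
    fn <- sum(width(tm)) - tp
    tn <- sum(chrom_sizes) - tp - fp - fn
    base_p <- tp / (tp + fp)
    base_r <- tp / (tp + fn)
    base_acc <- (tp + tn) / sum(chrom_sizes)
  }
  list(
    interval = data.frame(precision = int_p, recall = int_r,
                          f1 = f1_of(int_p, int_r)),
    base = data.frame(precision = base_p, recall = base_r,
                      f1 = f1_of(base_p, base_r), accuracy = base_acc)
  )
}
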