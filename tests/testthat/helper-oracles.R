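# Brute-force oracles, independent of the package's GRanges-based code
# paths, plus small fixture builders shared across test files.

# per-base boolean mask of a BED-style interval data frame over one genome
mask_from_df <- function(df, chrom_sizes) {
  masks <- lapply(chrom_sizes, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    masks[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  masks
}

# interval union (plus gap-bridging) reconstructed from a mask
oracle_merge <- function(df, chrom_sizes, max_gap = 0) {
  masks <- mask_from_df(df, chrom_sizes)
  out <- NULL
  for (chrom in names(masks)) {
    m <- masks[[chrom]]
    if (max_gap > 0) {
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in seq_along(r$values)) {
        interior <- k > 1 && k < length(r$values)
        if (!r$values[k] && interior && r$lengths[k] <= max_gap) {
          m[starts[k]:ends[k]] <- TRUE
        }
      }
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep)) {
      out <- rbind(out, data.frame(chrom = chrom, start = starts[keep] - 1,
                                   end = ends[keep]))
    }
  }
  out
}

# O(n*m) pairwise overlap scan
oracle_count_overlapping <- function(qdf, sdf) {
  hit <- logical(nrow(qdf))
  for (i in seq_len(nrow(qdf))) {
    for (j in seq_len(nrow(sdf))) {
      if (qdf$chrom[i] == sdf$chrom[j] &&
          max(qdf$start[i], sdf$start[j]) < min(qdf$end[i], sdf$end[j])) {
        hit[i] <- TRUE
        break
      }
    }
  }
  list(n_query_hit = sum(hit), fraction = sum(hit) / nrow(qdf))
}

# random BED-style interval table
random_intervals_df <- function(n, chrom_sizes, max_width = 50) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_sizes[chrom] - w))
  data.frame(chrom = chrom, start = start, end = start + w)
}

# Anchored-regex oracle for the canonical motif grammar: does a match of
# exactly width w start at 1-based position p? The scan policy (leftmost
# position, shortest width, resume after match end) is replayed on top.
oracle_scan_fwd <- function(s) {
  L <- nchar(s)
  pat <- "^G{3,5}[ACGTN]{1,7}G{3,5}[ACGTN]{1,7}G{3,5}[ACGTN]{1,7}G{3,5}$"
  hits <- NULL
  p <- 1
  while (p <= L - 14) {
    widths <- 15:min(41, L - p + 1)
    if (length(widths)) {
      subs <- substring(s, p, p + widths - 1)
      ok <- grepl(pat, subs)
      if (any(ok)) {
        w <- widths[which(ok)[1]]
        hits <- rbind(hits, data.frame(start = p, end = p + w - 1))
        p <- p + w
        next
      }
    }
    p <- p + 1
  }
  hits
}

# random test string for scanner-vs-oracle checks: uniform, G-rich, or a
# planted motif instance with point mutations and random flanks
random_scan_string <- function() {
  kind <- sample(3, 1)
  if (kind < 3) {
    L <- sample(15:41, 1)
    pG <- if (kind == 1) 0.25 else 0.55
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - pG) / 3, (1 - pG) / 3, pG, (1 - pG) / 3)),
          collapse = "")
  } else {
    runs <- sample(3:5, 4, replace = TRUE)
    loops <- sample(1:7, 3, replace = TRUE)
    ch <- c(rep("G", runs[1]), sample(c("A", "C", "T"), loops[1], TRUE),
            rep("G", runs[2]), sample(c("A", "C", "T"), loops[2], TRUE),
            rep("G", runs[3]), sample(c("A", "C", "T"), loops[3], TRUE),
            rep("G", runs[4]))
    n_mut <- sample(0:2, 1)
    if (n_mut > 0) {
      at <- sample(length(ch), n_mut)
      ch[at] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
    }
    pre <- sample(0:4, 1); post <- sample(0:4, 1)
    paste(c(sample(c("A", "C", "G", "T"), pre, TRUE), ch,
            sample(c("A", "C", "G", "T"), post, TRUE)), collapse = "")
  }
}

revcomp_chr <- function(s) {
  paste(rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[
    strsplit(s, "")[[1]]]), collapse = "")
}

# both-strand oracle as (start, end, strand) data frame, 1-based closed
oracle_scan_both <- function(s) {
  L <- nchar(s)
  fwd <- oracle_scan_fwd(s)
  if (!is.null(fwd)) fwd$strand <- "+"
  rev_hits <- oracle_scan_fwd(revcomp_chr(s))
  if (!is.null(rev_hits)) {
    rev_hits <- data.frame(start = L - rev_hits$end + 1,
                           end = L - rev_hits$start + 1, strand = "-")
  }
  out <- rbind(fwd, rev_hits)
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# full-enumeration two-sided Fisher p for a 2x2 table with fixed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-built two-gene annotation on one chromosome for region tests:
# gene A on + strand, gene B on - strand, with explicit UTR tracks
tiny_tx_set <- function() {
  tx <- c(
    gintervals("chr1", 10000, 14000, strand = "+"),
    gintervals("chr1", 30000, 34000, strand = "-")
  )
  S4Vectors::mcols(tx)$gene_id <- c("gA", "gB")
  S4Vectors::mcols(tx)$transcript_id <- c("gA.t1", "gB.t1")
  exons <- c(
    gintervals("chr1", c(10000, 13500), c(10400, 14000), strand = "+"),
    gintervals("chr1", c(30000, 33600), c(30500, 34000), strand = "-")
  )
  S4Vectors::mcols(exons)$gene_id <- rep(c("gA", "gB"), each = 2)
  S4Vectors::mcols(exons)$transcript_id <- rep(c("gA.t1", "gB.t1"), each = 2)
  # 5'UTRs extend past the +200 promoter edge so the label is reachable
  utr5 <- c(gintervals("chr1", 10000, 10400, strand = "+"),
            gintervals("chr1", 33600, 34000, strand = "-"))
  utr3 <- c(gintervals("chr1", 13800, 14000, strand = "+"),
            gintervals("chr1", 30000, 30150, strand = "-"))
  S4Vectors::mcols(utr5)$gene_id <- c("gA", "gB")
  S4Vectors::mcols(utr5)$transcript_id <- c("gA.t1", "gB.t1")
  S4Vectors::mcols(utr3)$gene_id <- c("gA", "gB")
  S4Vectors::mcols(utr3)$transcript_id <- c("gA.t1", "gB.t1")
  transcript_set(tx, exons, utr5 = utr5, utr3 = utr3)
}

# small synthetic world reused by several test files
small_world <- function(seed = 42L, n_divergent = 0L, fraction_with_pELS = 1) {
  cfg <- synth_config(genome_length = 200000L, n_chroms = 1L,
                      n_planted_gq = 40L, n_genes = 12L, seed = seed)
  ann <- gen_annotation(cfg, fraction_with_pELS = fraction_with_pELS,
                        n_divergent_pairs = n_divergent)
  list(cfg = cfg, ann = ann)
}
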