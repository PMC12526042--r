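## Seeded synthetic-data generator: genomes with planted canonical GQ motifs,
## transcript annotation with cCREs placed relative to the TSS, leveled GQ
## call sets with dropout/jitter, and multiome-style linkage tables with
## planted sign structure. Every generator records its ground truth so the
## downstream modules can be tested against known answers.

#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs shared by the `gen_*()` generators. Defaults describe
#' the standing study conditions used throughout the package's tests: a
#' 2-Mb two-chromosome genome at human-like GC content with 300 planted
#' canonical GQ motifs and 50 genes, and an EndoQuad-shaped confidence-level
#' mix (most calls weakly supported, about a third at levels 4-6, 7% at
#' level 6).
#'
#' @param genome_length chromosome length in bp.
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param gc_content background GC fraction in (0, 1); bases are i.i.d.
#' @param n_planted_gq total number of planted canonical motifs.
#' @param n_genes total number of genes.
#' @param levels_model named numeric vector: for each confidence level
#'   ("1".."6"), the probability that a truth interval is emitted at that
#'   level by [gen_gq_calls()]. Probabilities must sum to at most 1; the
#'   remainder is dropout.
#' @param linkage_noise_sd standard deviation of the background linkage
#'   correlation noise.
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 1e6L,
                         n_chroms = 2L,
                         gc_content = 0.41,
                         n_planted_gq = 300L,
                         n_genes = 50L,
                         levels_model = c("1" = 0.31, "2" = 0.18, "3" = 0.15,
                                          "4" = 0.14, "5" = 0.15, "6" = 0.07),
                         linkage_noise_sd = 0.15,
                         seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1, n_planted_gq >= 0,
            genome_length >= 10 * 41, n_chroms >= 1)
  if (any(levels_model < 0) || any(levels_model > 1) || sum(levels_model) > 1 + 1e-12) {
    stop("levels_model must be probabilities summing to at most 1")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms),
                 gc_content = gc_content,
                 n_planted_gq = as.integer(n_planted_gq),
                 n_genes = as.integer(n_genes),
                 levels_model = levels_model,
                 linkage_noise_sd = linkage_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One random canonical motif instance: four G-runs of 3-5 separated by three
# loops of 1-7 non-G bases (written on the motif's own strand).
random_motif_instance <- function() {
  runs <- sample(3:5, 4, replace = TRUE)
  loops <- sample(1:7, 3, replace = TRUE)
  loop_seq <- lapply(loops, function(l) sample(c("A", "C", "T"), l, replace = TRUE))
  chars <- c(
    rep("G", runs[1]), loop_seq[[1]],
    rep("G", runs[2]), loop_seq[[2]],
    rep("G", runs[3]), loop_seq[[3]],
    rep("G", runs[4])
  )
  list(chars = chars, runs = runs, loops = loops)
}

#' Generate a synthetic genome with planted canonical GQ motifs
#'
#' Background bases are i.i.d. at the configured GC content. Each planted
#' motif is a random instance of the canonical grammar (four G-runs of 3-5
#' guanines separated by loops of 1-7 non-G bases, minimum width 15 bp),
#' written on a uniformly chosen strand (a minus-strand motif appears as
#' C-runs on the forward sequence). Motifs are placed without overlapping
#' one another and with 2-bp A/T buffer flanks so a planted instance is
#' never extended by neighbouring background guanines.
#'
#' @param config a [synth_config()].
#' @return A list with `genome` (named `DNAStringSet`), `truth` (stranded
#'   `GRanges` of the planted motifs, one metadata column `width_bp`), and
#'   `chrom_sizes`.
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  L <- config$genome_length
  p_gc <- config$gc_content
  base_probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2,
                  G = p_gc / 2, T = (1 - p_gc) / 2)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$n_planted_gq,
                              length.out = config$n_chroms + 1)))
  seqs <- character(config$n_chroms)
  truth <- vector("list", config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    chars <- sample(names(base_probs), L, replace = TRUE, prob = base_probs)
    n_here <- per_chrom[ci]
    occupied <- IRanges()
    placed_start <- integer(0); placed_end <- integer(0)
    placed_strand <- character(0)
    attempts <- 0L
    while (length(placed_start) < n_here) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(1L, n_here)) {
        stop("could not place all motifs without overlap; genome too crowded")
      }
      inst <- random_motif_instance()
      w <- length(inst$chars)
      s <- sample.int(L - w - 4L, 1L) + 2L  # 1-based, leave room for buffers
      cand <- IRanges(s - 2L, s + w + 1L)   # motif plus 2-bp buffers
      if (length(findOverlaps(cand, occupied))) next
      strand_i <- sample(c("+", "-"), 1L)
      motif_chars <- inst$chars
      if (strand_i == "-") {
        motif_chars <- rev(c(A = "T", C = "G", G = "C", T = "A")[motif_chars])
      }
      chars[s:(s + w - 1L)] <- motif_chars
      chars[c(s - 2L, s - 1L, s + w, s + w + 1L)] <-
        sample(c("A", "T"), 4L, replace = TRUE)
      occupied <- c(occupied, cand)
      placed_start <- c(placed_start, s)
      placed_end <- c(placed_end, s + w - 1L)
      placed_strand <- c(placed_strand, strand_i)
    }
    seqs[ci] <- paste(chars, collapse = "")
    truth[[ci]] <- if (length(placed_start)) {
      GRanges(chrom_names[ci], IRanges(placed_start, placed_end),
              strand = placed_strand)
    } else {
      GRanges()
    }
  }
  genome <- DNAStringSet(setNames(seqs, chrom_names))
  truth <- sort(unlist(GRangesList(truth), use.names = FALSE),
                ignore.strand = TRUE)
  mcols(truth)$width_bp <- width(truth)
  list(genome = genome, truth = truth, chrom_sizes = chrom_sizes_of(genome))
}

#' Generate synthetic transcript annotation and cCRE tracks
#'
#' Genes are laid out in evenly spaced slots. Each gene gets 1-3 transcripts
#' (shared or offset TSS) on a random strand with 2-3 exons, a promoter-like
#' element (PLS) centered on the TSS, optionally a proximal enhancer-like
#' element (pELS) that overlaps the promoter window (-1000/+200 around the
#' TSS) but extends beyond it, and a distal element (dELS) far from any TSS.
#' `n_divergent_pairs` reserves slots for head-to-head gene pairs whose
#' promoter windows overlap, with one shared pELS inside both windows - the
#' configuration a discordant enhancer needs.
#'
#' @param config a [synth_config()].
#' @param fraction_with_pELS fraction of genes receiving an overlapping
#'   pELS (1 guarantees every gene forms at least one pEP pair, 0 none).
#' @param n_divergent_pairs number of divergent gene pairs sharing a pELS.
#' @return A list with `tx_set` (a [transcript_set()]), `ccres` (`GRanges`
#'   with `class` in `{PLS, pELS, dELS}` and a standard-normal conservation
#'   `score`), `divergent` (data frame describing the shared-pELS gene
#'   pairs) and `chrom_sizes`.
#' @export
gen_annotation <- function(config, fraction_with_pELS = 1,
                           n_divergent_pairs = 0L) {
  stopifnot(inherits(config, "synth_config"),
            fraction_with_pELS >= 0, fraction_with_pELS <= 1)
  set.seed(config$seed + 1L)
  L <- config$genome_length
  n_units <- config$n_genes  # a divergent pair occupies one unit (two genes)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, n_units, length.out = config$n_chroms + 1)))
  slot <- floor(L / max(per_chrom, 1))
  if (slot < 12000) stop("gene slots too small; reduce n_genes or grow genome")

  tx_list <- list(); exon_list <- list(); ccre_list <- list()
  div_rows <- list()
  gene_counter <- 0L
  pair_counter <- 0L
  n_div_left <- n_divergent_pairs
  with_pels <- function() runif(1) < fraction_with_pELS

  add_gene <- function(chrom, tss, strand_g, gene_id) {
    # Returns list(tx, exons) for one gene; tss is 1-based.
    n_tx <- sample(1:3, 1)
    offs <- c(0L, sample(c(0L, 150L, 300L), 2, replace = TRUE))[seq_len(n_tx)]
    txs <- list(); exs <- list()
    for (t in seq_len(n_tx)) {
      tss_t <- if (strand_g == "+") tss + offs[t] else tss - offs[t]
      len_t <- sample(2000:3500, 1)
      if (strand_g == "+") {
        s <- tss_t; e <- tss_t + len_t - 1L
      } else {
        e <- tss_t; s <- tss_t - len_t + 1L
      }
      tid <- sprintf("%s.t%d", gene_id, t)
      tx <- GRanges(chrom, IRanges(s, e), strand = strand_g)
      mcols(tx)$gene_id <- gene_id; mcols(tx)$transcript_id <- tid
      # two exons: one at each end of the span, intron in between
      e1 <- GRanges(chrom, IRanges(s, s + sample(150:300, 1)), strand = strand_g)
      e2 <- GRanges(chrom, IRanges(e - sample(150:300, 1), e), strand = strand_g)
      ex <- c(e1, e2)
      mcols(ex)$gene_id <- gene_id; mcols(ex)$transcript_id <- tid
      txs[[t]] <- tx; exs[[t]] <- ex
    }
    list(tx = unlist(GRangesList(txs)), exons = unlist(GRangesList(exs)))
  }

  for (ci in seq_len(config$n_chroms)) {
    for (ui in seq_len(per_chrom[ci])) {
      anchor <- (ui - 1L) * slot + 4500L  # leave margin for upstream elements
      chrom <- chrom_names[ci]
      if (n_div_left > 0L) {
        # Divergent pair: gene A on '-' with TSS at anchor, gene B on '+'
        # with TSS 600 bp to the right; promoter windows overlap and one
        # shared pELS sits inside both.
        n_div_left <- n_div_left - 1L
        pair_counter <- pair_counter + 1L
        gene_counter <- gene_counter + 1L
        ga <- sprintf("g%03d", gene_counter)
        gene_counter <- gene_counter + 1L
        gb <- sprintf("g%03d", gene_counter)
        tss_a <- anchor; tss_b <- anchor + 600L
        a <- add_gene(chrom, tss_a, "-", ga)
        b <- add_gene(chrom, tss_b, "+", gb)
        tx_list <- c(tx_list, list(a$tx, b$tx))
        exon_list <- c(exon_list, list(a$exons, b$exons))
        pls <- GRanges(chrom, IRanges(c(tss_a - 150L, tss_b - 150L),
                                      c(tss_a + 149L, tss_b + 149L)))
        mcols(pls)$class <- "PLS"
        shared <- GRanges(chrom, IRanges(tss_a + 220L, tss_a + 480L))
        mcols(shared)$class <- "pELS"
        ccre_list <- c(ccre_list, list(pls, shared))
        div_rows[[pair_counter]] <- data.frame(
          chrom = chrom, pels_start = start(shared) - 1L,
          pels_end = end(shared),
          gene_minus = ga, gene_plus = gb,
          tss_minus = tss_a - 1L, tss_plus = tss_b - 1L
        )
      } else {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("g%03d", gene_counter)
        strand_g <- sample(c("+", "-"), 1)
        tss <- anchor
        g <- add_gene(chrom, tss, strand_g, gid)
        tx_list <- c(tx_list, list(g$tx))
        exon_list <- c(exon_list, list(g$exons))
        pls <- GRanges(chrom, IRanges(tss - 150L, tss + 149L))
        mcols(pls)$class <- "PLS"
        ccre_list <- c(ccre_list, list(pls))
        if (with_pels()) {
          # straddles the upstream promoter edge: ~100 bp inside the
          # -1000/+200 window, the rest outside it
          pels <- if (strand_g == "+") {
            GRanges(chrom, IRanges(tss - 1300L, tss - 901L))
          } else {
            GRanges(chrom, IRanges(tss + 901L, tss + 1300L))
          }
          mcols(pels)$class <- "pELS"
          ccre_list <- c(ccre_list, list(pels))
        }
        dels <- if (strand_g == "+") {
          GRanges(chrom, IRanges(tss + 4000L, tss + 4299L))
        } else {
          GRanges(chrom, IRanges(max(1L, tss - 4299L), tss - 4000L))
        }
        mcols(dels)$class <- "dELS"
        ccre_list <- c(ccre_list, list(dels))
      }
    }
  }
  transcripts <- unlist(GRangesList(tx_list), use.names = FALSE)
  exons <- unlist(GRangesList(exon_list), use.names = FALSE)
  ccres <- unlist(GRangesList(ccre_list), use.names = FALSE)
  mcols(ccres)$score <- rnorm(length(ccres))
  chrom_sizes <- setNames(rep(L, config$n_chroms), chrom_names)
  validate_intervals(transcripts, chrom_sizes)
  validate_intervals(ccres, chrom_sizes)
  divergent <- if (length(div_rows)) do.call(rbind, div_rows) else
    data.frame(chrom = character(), pels_start = integer(),
               pels_end = integer(), gene_minus = character(),
               gene_plus = character(), tss_minus = integer(),
               tss_plus = integer())
  list(tx_set = transcript_set(transcripts, exons),
       ccres = ccres, divergent = divergent, chrom_sizes = chrom_sizes)
}

#' Generate a leveled GQ call set from planted truth
#'
#' Emulates an aggregated experimental call set: each truth interval is
#' emitted at confidence level k with probability `levels_model[k]` and
#' dropped otherwise; boundaries can be jittered; false-positive intervals
#' can be added at a given rate.
#'
#' @param truth stranded `GRanges` of planted motifs (from [gen_genome()]).
#' @param levels_model named probability vector over levels (see
#'   [synth_config()]).
#' @param seed integer seed.
#' @param fp_rate expected number of false-positive calls as a fraction of
#'   the truth count.
#' @param jitter maximum absolute boundary shift in bp (uniform).
#' @param chrom_sizes named lengths, required when `jitter > 0` or
#'   `fp_rate > 0` so emitted intervals stay on the chromosome.
#' @return `GRanges` with integer `level` and logical `is_fp` columns.
#' @export
gen_gq_calls <- function(truth, levels_model, seed = 1L, fp_rate = 0,
                         jitter = 0L, chrom_sizes = NULL) {
  if (any(levels_model < 0) || sum(levels_model) > 1 + 1e-12) {
    stop("levels_model must be probabilities summing to at most 1")
  }
  if ((jitter > 0 || fp_rate > 0) && is.null(chrom_sizes)) {
    stop("chrom_sizes required when jitter or fp_rate is positive")
  }
  set.seed(seed)
  lev_names <- as.integer(names(levels_model))
  cum <- cumsum(levels_model)
  u <- runif(length(truth))
  pick <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
  keep <- pick >= 1 & pick <= length(levels_model) & u < cum[length(cum)]
  calls <- truth[keep]
  mcols(calls) <- NULL
  mcols(calls)$level <- lev_names[pick[keep]]
  mcols(calls)$is_fp <- FALSE
  if (jitter > 0 && length(calls)) {
    ds <- sample(-jitter:jitter, length(calls), replace = TRUE)
    de <- sample(-jitter:jitter, length(calls), replace = TRUE)
    ns <- pmax(1L, start(calls) + ds)
    lim <- chrom_sizes[as.character(seqnames(calls))]
    ne <- pmin(lim, end(calls) + de)
    bad <- ns > ne
    ns[bad] <- start(calls)[bad]; ne[bad] <- end(calls)[bad]
    ranges(calls) <- IRanges(ns, ne)
  }
  if (fp_rate > 0) {
    n_fp <- rbinom(1L, length(truth), min(1, fp_rate))
    if (n_fp > 0) {
      chroms <- sample(names(chrom_sizes), n_fp, replace = TRUE)
      w <- sample(15:41, n_fp, replace = TRUE)
      s <- floor(runif(n_fp, 1, chrom_sizes[chroms] - w))
      fp <- GRanges(chroms, IRanges(s, s + w - 1L),
                    strand = sample(c("+", "-"), n_fp, replace = TRUE))
      mcols(fp)$level <- sample(lev_names, n_fp, replace = TRUE,
                                prob = levels_model / sum(levels_model))
      mcols(fp)$is_fp <- TRUE
      calls <- c(calls, fp)
    }
  }
  sort(calls, ignore.strand = TRUE)
}

#' Generate a multiome-style feature-linkage table
#'
#' Emits (ATAC peak, gene, correlation, sample) records emulating vendor
#' feature linkages. For each gene selected as "open", a ~500-bp peak is
#' placed so that it overlaps both the gene's promoter window and its pELS
#' (when one exists), with correlation drawn from a truncated normal. For
#' each planted discordant enhancer, one shared peak over the divergent
#' pair's pELS is linked with a positive correlation to one gene and a
#' negative correlation to the adjacent gene.
#'
#' @param annotation output of [gen_annotation()].
#' @param plant_discordant number of discordant enhancers to plant; requires
#'   at least that many divergent pairs in the annotation.
#' @param noise_mean,noise_sd background correlation distribution
#'   (truncated to `[-1, 1]`); the sign is positive with probability
#'   `1 - p_negative`.
#' @param p_negative fraction of background links with negative sign.
#' @param open_fraction fraction of genes that receive a peak at all.
#' @param r_pos,r_neg correlations attached to each planted discordant
#'   enhancer's two links.
#' @param sample_tag sample label written to every record.
#' @param seed integer seed.
#' @return A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open peak coordinates), `gene_id`, `correlation`, `sample`.
#' @export
gen_linkages <- function(annotation, plant_discordant = 0L,
                         noise_mean = 0.5, noise_sd = 0.15,
                         p_negative = 0.1, open_fraction = 1,
                         r_pos = 0.67, r_neg = -0.61,
                         sample_tag = "s1", seed = 1L) {
  stopifnot(r_pos > 0, r_neg < 0)
  if (plant_discordant > nrow(annotation$divergent)) {
    stop("annotation has only ", nrow(annotation$divergent),
         " divergent pairs; cannot plant ", plant_discordant)
  }
  set.seed(seed)
  tx <- annotation$tx_set$transcripts
  tss <- resize(tx, 1L, fix = "start")
  genes <- unique(mcols(tx)$gene_id)
  div_genes <- unique(c(annotation$divergent$gene_minus,
                        annotation$divergent$gene_plus))
  rows <- list()
  trunc_r <- function(n) {
    r <- abs(rnorm(n, noise_mean, noise_sd))
    r <- pmin(r, 1)
    sgn <- ifelse(runif(n) < p_negative, -1, 1)
    r * sgn
  }
  bg_genes <- setdiff(genes, div_genes)
  bg_genes <- bg_genes[runif(length(bg_genes)) < open_fraction]
  for (g in bg_genes) {
    tx_g <- tx[mcols(tx)$gene_id == g]
    t1 <- tx_g[1]
    tss1 <- if (as.character(strand(t1)) == "+") start(t1) else end(t1)
    # peak straddling the upstream promoter edge -> overlaps the pELS
    # (placed at 900-1300 bp upstream) and the promoter window
    pk <- if (as.character(strand(t1)) == "+") {
      c(tss1 - 1050L, tss1 - 551L)
    } else {
      c(tss1 + 551L, tss1 + 1050L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(t1)), start = pk[1] - 1L, end = pk[2],
      gene_id = g, correlation = trunc_r(1), sample = sample_tag
    )
  }
  if (plant_discordant > 0L) {
    dv <- annotation$divergent[seq_len(plant_discordant), , drop = FALSE]
    for (i in seq_len(nrow(dv))) {
      ps <- dv$pels_start[i] - 40L  # 0-based peak containing the pELS
      pe <- dv$pels_end[i] + 40L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = dv$chrom[i], start = ps, end = pe,
        gene_id = dv$gene_plus[i], correlation = r_pos, sample = sample_tag
      )
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = dv$chrom[i], start = ps, end = pe,
        gene_id = dv$gene_minus[i], correlation = r_neg, sample = sample_tag
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Null model for GQ placement in pEP universes
#'
#' For calibration of the observed-versus-expected pair enrichment, GQs
#' must flag promoters and enhancers independently. `null_gq_model()`
#' precomputes, for every transcript promoter, its largest sub-interval
#' free of any pELS, and for every pELS its largest sub-interval free of
#' any promoter (the generator places pELS straddling the promoter edge,
#' so both zones exist). `gen_null_gq()` then plants a fixed-width GQ in
#' each promoter zone with probability `p_promoter` and in each pELS zone
#' with probability `p_enhancer`, independently - so the two flags of any
#' pair are independent by construction.
#'
#' @param annotation output of [gen_annotation()].
#' @param up,down promoter geometry.
#' @param gq_width planted GQ width in bp.
#' @return `null_gq_model`: a list with `prom_zones` and `enh_zones`
#'   (`GRanges`).
#' @export
null_gq_model <- function(annotation, up = 1000L, down = 200L,
                          gq_width = 20L) {
  prom <- promoter_of(annotation$tx_set, up = up, down = down)
  pels <- annotation$ccres[mcols(annotation$ccres)$class == "pELS"]
  pels_all <- reduce(granges(pels)); strand(pels_all) <- "*"
  prom_all <- reduce(granges(prom)); strand(prom_all) <- "*"
  largest_free <- function(x, blocked) {
    out <- vector("list", length(x))
    for (i in seq_along(x)) {
      xi <- granges(x[i]); strand(xi) <- "*"
      pieces <- setdiff(xi, blocked)
      pieces <- pieces[width(pieces) >= gq_width + 2L]
      out[[i]] <- if (length(pieces)) {
        pieces[which.max(width(pieces))]
      } else {
        GRanges()
      }
    }
    unlist(GRangesList(out), use.names = FALSE)
  }
  list(prom_zones = largest_free(prom, pels_all),
       enh_zones = largest_free(pels, prom_all),
       gq_width = as.integer(gq_width))
}

#' @rdname null_gq_model
#' @param model a `null_gq_model()`.
#' @param p_promoter,p_enhancer per-zone planting probabilities.
#' @param seed integer seed.
#' @return `gen_null_gq`: a `GRanges` of planted GQs.
#' @export
gen_null_gq <- function(model, p_promoter = 0.5, p_enhancer = 0.5,
                        seed = 1L) {
  set.seed(seed)
  w <- model$gq_width
  place <- function(zones, p) {
    keep <- zones[runif(length(zones)) < p]
    if (!length(keep)) return(GRanges())
    off <- floor(runif(length(keep)) * (width(keep) - w))
    GRanges(seqnames(keep), IRanges(start(keep) + off, width = w))
  }
  sort(c(place(model$prom_zones, p_promoter),
         place(model$enh_zones, p_enhancer)), ignore.strand = TRUE)
}
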