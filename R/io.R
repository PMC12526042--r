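## File-format boundary: BED, GTF, FASTA, chromosome sizes.
## BED is read/written 0-based half-open verbatim; GTF (1-based inclusive)
## is converted to the internal representation on read.

#' Read a BED file of genomic intervals
#'
#' Reads a 3-6 column BED file. Coordinates are taken 0-based half-open
#' verbatim; column 4 becomes `name`, column 5 `score`, column 6 `strand`.
#' Lines failing basic BED syntax raise an error naming the file and line.
#'
#' @param path path to a BED file.
#' @param chrom_sizes optional named vector; when supplied every interval is
#'   validated against it.
#' @return A `GRanges` with `name`/`score` metadata columns where present.
#' @seealso [write_bed()], [read_gq_bed()], [read_ccre_bed()]
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) >= 3 &&
      !is.na(suppressWarnings(s <- as.numeric(f[2]))) &&
      !is.na(suppressWarnings(e <- as.numeric(f[3]))) &&
      s >= 0 && s < e
    if (!ok) {
      stop(sprintf("malformed BED line %d in %s: '%s'",
                   lineno[i], path, lines[lineno[i]]))
    }
  }
  if (!length(fields)) return(GRanges())
  n <- lengths(fields)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  name <- ifelse(n >= 4, vapply(fields, `[`, "", 4L), NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(n >= 5, vapply(fields, `[`, "", 5L), NA))
  )
  strand <- ifelse(n >= 6, vapply(fields, `[`, "", 6L), "*")
  gr <- gintervals(chrom, start, end,
                   strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  if (any(n >= 4)) mcols(gr)$name <- name
  if (any(n >= 5)) mcols(gr)$score <- score
  if (!is.null(chrom_sizes)) validate_intervals(gr, chrom_sizes)
  gr
}

#' Write intervals to a BED file
#'
#' Writes BED6 when `name`, `score` or strand information is present, BED3
#' otherwise. Round-trips losslessly with [read_bed()].
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_bed <- function(gr, path) {
  df <- gr_to_bed_df(gr)
  has6 <- any(df$strand != "*") || !is.null(df$name) || !is.null(df$score)
  if (has6) {
    out <- data.frame(
      chrom = df$chrom, start = df$start, end = df$end,
      name = if (is.null(df$name)) "." else ifelse(is.na(df$name), ".", df$name),
      score = if (is.null(df$score)) 0 else ifelse(is.na(df$score), 0, df$score),
      strand = df$strand
    )
  } else {
    out <- df[c("chrom", "start", "end")]
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a leveled GQ call set from BED
#'
#' GQ call sets carry a confidence level (1-6, EndoQuad-style: the number of
#' independent experiments supporting the call) in the BED score column.
#'
#' @param path BED file; column 5 is the confidence level.
#' @param method optional source-method tag attached to every call.
#' @param chrom_sizes optional validation target.
#' @return A `GRanges` with integer `level` and character `method` columns.
#' @export
read_gq_bed <- function(path, method = NA_character_, chrom_sizes = NULL) {
  gr <- read_bed(path, chrom_sizes)
  if (is.null(mcols(gr)$score)) {
    stop("GQ BED ", path, " lacks a level column (BED column 5)")
  }
  mcols(gr)$level <- as.integer(mcols(gr)$score)
  mcols(gr)$score <- NULL
  mcols(gr)$method <- method
  gr
}

#' Write a leveled GQ call set to BED
#' @param gq `GRanges` with a `level` metadata column.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_gq_bed <- function(gq, path) {
  out <- granges(gq)
  mcols(out)$name <- if (is.null(mcols(gq)$method)) "." else mcols(gq)$method
  mcols(out)$score <- mcols(gq)$level
  write_bed(out, path)
}

#' Read a cCRE track from BED
#'
#' Candidate cis-regulatory elements with the class label (PLS, pELS or
#' dELS) in BED column 4 and an optional numeric score (e.g. a phyloP
#' conservation score) in column 5.
#'
#' @inheritParams read_gq_bed
#' @return A `GRanges` with `class` (and `score` when present) columns.
#' @export
read_ccre_bed <- function(path, chrom_sizes = NULL) {
  gr <- read_bed(path, chrom_sizes)
  if (is.null(mcols(gr)$name)) {
    stop("cCRE BED ", path, " lacks a class column (BED column 4)")
  }
  mcols(gr)$class <- mcols(gr)$name
  mcols(gr)$name <- NULL
  bad <- setdiff(unique(mcols(gr)$class), c("PLS", "pELS", "dELS"))
  if (length(bad)) {
    warning("unrecognized cCRE class label(s): ", paste(bad, collapse = ", "))
  }
  gr
}

#' Write a cCRE track to BED
#' @param ccres `GRanges` with a `class` column (and optional `score`).
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_ccre_bed <- function(ccres, path) {
  out <- granges(ccres)
  mcols(out)$name <- mcols(ccres)$class
  mcols(out)$score <- if (is.null(mcols(ccres)$score)) 0 else mcols(ccres)$score
  write_bed(out, path)
}

#' Transcript models
#'
#' A light container for transcript annotation: a `transcripts` `GRanges`
#' (one range per transcript span, metadata `gene_id`, `transcript_id`,
#' strand `+`/`-`) plus per-transcript `exons` and optional UTR tracks. The
#' strand-aware TSS of each transcript is its 5' end: `start` on `+`,
#' `end` on `-`.
#'
#' @param transcripts `GRanges` of transcript spans with `gene_id` and
#'   `transcript_id` metadata and strand `+` or `-`.
#' @param exons `GRanges` of exons with a `transcript_id` column; must lie
#'   within their transcript's span.
#' @param utr5,utr3 optional `GRanges` of UTRs with `transcript_id`; when
#'   absent, region classification collapses UTR labels into `exon`.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons = GRanges(),
                           utr5 = GRanges(), utr3 = GRanges()) {
  need <- c("gene_id", "transcript_id")
  if (!all(need %in% names(mcols(transcripts)))) {
    stop("transcripts need gene_id and transcript_id metadata columns")
  }
  if (any(!as.character(strand(transcripts)) %in% c("+", "-"))) {
    stop("every transcript must be stranded (+ or -)")
  }
  if (anyDuplicated(mcols(transcripts)$transcript_id)) {
    stop("duplicate transcript_id")
  }
  if (length(exons)) {
    if (!"transcript_id" %in% names(mcols(exons))) {
      stop("exons need a transcript_id column")
    }
    span <- transcripts[match(mcols(exons)$transcript_id,
                              mcols(transcripts)$transcript_id)]
    if (anyNA(span)) stop("exon refers to unknown transcript_id")
    inside <- as.character(seqnames(exons)) == as.character(seqnames(span)) &
      start(exons) >= start(span) & end(exons) <= end(span)
    if (!all(inside)) stop("exon outside its transcript span")
  }
  structure(list(transcripts = transcripts, exons = exons,
                 utr5 = utr5, utr3 = utr3),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d genes, %d exons\n",
              length(x$transcripts),
              length(unique(mcols(x$transcripts)$gene_id)),
              length(x$exons)))
  invisible(x)
}

#' Strand-aware TSS positions of a transcript set
#'
#' @param tx_set a [transcript_set()].
#' @return A width-1 `GRanges`, one TSS per transcript (5' end).
#' @export
tss_of <- function(tx_set) {
  resize(tx_set$transcripts, width = 1L, fix = "start")
}

#' Read transcript models from a GTF file
#'
#' Parses `transcript`, `exon` and (when present) `five_prime_utr` /
#' `three_prime_utr` features. GTF 1-based inclusive coordinates are
#' converted to the internal representation on read.
#'
#' @param path GTF file with `gene_id` and `transcript_id` attributes.
#' @return A [transcript_set()].
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  pick <- function(type) {
    out <- gr[mcols(gr)$type == type]
    mcols(out) <- mcols(out)[c("gene_id", "transcript_id")]
    out
  }
  tx <- pick("transcript")
  if (!length(tx)) stop("no transcript features in ", path)
  transcript_set(
    transcripts = tx,
    exons = pick("exon"),
    utr5 = pick("five_prime_utr"),
    utr3 = pick("three_prime_utr")
  )
}

#' Write transcript models to a GTF file
#' @param tx_set a [transcript_set()].
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_gtf_transcripts <- function(tx_set, path) {
  pieces <- list(transcript = tx_set$transcripts, exon = tx_set$exons,
                 five_prime_utr = tx_set$utr5, three_prime_utr = tx_set$utr3)
  pieces <- pieces[lengths(pieces) > 0]
  all <- unlist(GRangesList(lapply(pieces, granges)), use.names = FALSE)
  mcols(all)$type <- rep(names(pieces), lengths(pieces))
  mcols(all)$gene_id <- unlist(lapply(pieces, function(p) mcols(p)$gene_id))
  mcols(all)$transcript_id <-
    unlist(lapply(pieces, function(p) mcols(p)$transcript_id))
  mcols(all)$source <- "gqpep"
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Read and write FASTA sequences
#'
#' Sequences are upper-cased on read.
#'
#' @param path FASTA file.
#' @return `read_fasta`: a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- readDNAStringSet(path)
  DNAStringSet(toupper(dss))
}

#' @rdname read_fasta
#' @param seqs a named `DNAStringSet` (or named character vector).
#' @return `write_fasta`: invisibly `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Chromosome sizes
#'
#' `chrom_sizes_of()` derives a named length vector from a genome;
#' `read_chrom_sizes()`/`write_chrom_sizes()` use the standard two-column
#' (name, length) TSV.
#'
#' @param genome a named `DNAStringSet`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes_of <- function(genome) {
  setNames(width(genome), names(genome))
}

#' @rdname chrom_sizes_of
#' @param path two-column TSV path.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  check_chrom_sizes(setNames(df$length, df$chrom))
}

#' @rdname chrom_sizes_of
#' @param chrom_sizes named vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
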