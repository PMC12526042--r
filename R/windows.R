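## Training-dataset construction from leveled GQ call sets: per-base
## positive tracks, fixed-width non-overlapping window labeling, negative
## sampling at a fixed ratio, and k-fold ensemble design.

#' Parameters for window-dataset construction
#'
#' Defaults reproduce the standard design: 512-bp non-overlapping windows,
#' positives defined by confidence levels >= 4, a 2x random sample of
#' negatives, and a 5-fold ensemble (each model trains on 80% of the data,
#' i.e. `1 - 1/k_folds`).
#'
#' @param window_size tile width in bp.
#' @param level_min minimum confidence level counted as positive signal.
#' @param neg_ratio negatives sampled per positive window.
#' @param k_folds number of folds/models.
#' @param seed integer seed for sampling and fold assignment.
#' @return A list of class `dataset_params`.
#' @export
dataset_params <- function(window_size = 512L, level_min = 4L, neg_ratio = 2L,
                           k_folds = 5L, seed = 1L) {
  stopifnot(window_size > 0, neg_ratio >= 0, k_folds >= 2)
  structure(list(window_size = as.integer(window_size),
                 level_min = as.integer(level_min),
                 neg_ratio = as.integer(neg_ratio),
                 k_folds = as.integer(k_folds),
                 train_pos_fraction = 1 - 1 / k_folds,
                 seed = as.integer(seed)),
            class = "dataset_params")
}

#' Per-base positive track from leveled GQ calls
#'
#' Marks every base that lies inside at least one call with level >=
#' `level_min`, as a per-chromosome logical run-length track.
#'
#' @param gq_calls `GRanges` with an integer `level` column.
#' @param level_min minimum level retained.
#' @param chrom_sizes named chromosome lengths; calls are validated against
#'   them and every chromosome gets a track (all-false when no call).
#' @return An `RleList` of logical tracks, one per chromosome.
#' @export
build_positive_track <- function(gq_calls, level_min = 4L, chrom_sizes) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  validate_intervals(gq_calls, chrom_sizes)
  keep <- gq_calls[mcols(gq_calls)$level >= level_min]
  keep <- granges(keep)
  strand(keep) <- "*"
  seqlevels(keep) <- names(chrom_sizes)
  seqlengths(keep) <- chrom_sizes
  cov <- coverage(keep)
  cov > 0
}

#' Tile chromosomes into labeled fixed-width windows
#'
#' Each chromosome is cut into non-overlapping `window_size`-bp windows
#' (trailing partial windows are dropped). A window is labeled positive iff
#' at least one of its bases is true in the positive track.
#'
#' @param track logical `RleList` from [build_positive_track()].
#' @param params a [dataset_params()].
#' @return A data frame with `chrom`, `index` (0-based tile ordinal),
#'   `start`, `end` (0-based half-open) and `label`
#'   (`"positive"`/`"negative"`).
#' @export
tile_and_label <- function(track, params = dataset_params()) {
  w <- params$window_size
  out <- lapply(names(track), function(chrom) {
    len <- length(track[[chrom]])
    n_win <- len %/% w
    if (n_win == 0L) return(NULL)
    starts <- (seq_len(n_win) - 1L) * w + 1L
    hit <- viewSums(Views(track[[chrom]], start = starts, width = w)) > 0
    data.frame(chrom = chrom, index = seq_len(n_win) - 1L,
               start = starts - 1L, end = starts - 1L + w,
               label = ifelse(hit, "positive", "negative"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sample negatives at a fixed ratio
#'
#' Keeps every positive window and a uniform without-replacement sample of
#' `neg_ratio` negatives per positive, drawn from the same tiling.
#' Deterministic given the seed in `params`.
#'
#' @param windows data frame from [tile_and_label()].
#' @param params a [dataset_params()].
#' @return The sampled subset, positives first, in genomic order within
#'   label.
#' @export
sample_negatives <- function(windows, params = dataset_params()) {
  pos <- windows[windows$label == "positive", , drop = FALSE]
  neg <- windows[windows$label == "negative", , drop = FALSE]
  n_need <- nrow(pos) * params$neg_ratio
  if (nrow(neg) < n_need) {
    stop(sprintf("insufficient negatives: need %d, have %d",
                 n_need, nrow(neg)))
  }
  set.seed(params$seed)
  take <- sort(sample.int(nrow(neg), n_need))
  out <- rbind(pos, neg[take, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Assign dataset windows to folds
#'
#' Splits the dataset into `k_folds` near-equal folds by a seeded uniform
#' shuffle, stratifying positives and negatives separately so each model
#' keeps the design's class balance. Model `j` trains on every window NOT
#' in fold `j`, so each window is excluded from exactly one model's
#' training set.
#'
#' @param dataset data frame from [sample_negatives()].
#' @param params a [dataset_params()].
#' @return `dataset` with an integer `fold` column in `1..k_folds`.
#' @export
assign_folds <- function(dataset, params = dataset_params()) {
  k <- params$k_folds
  n_pos <- sum(dataset$label == "positive")
  if (n_pos < k) {
    stop(sprintf("fewer positives (%d) than folds (%d)", n_pos, k))
  }
  set.seed(params$seed + 1L)
  fold <- integer(nrow(dataset))
  for (lab in c("positive", "negative")) {
    idx <- which(dataset$label == lab)
    if (!length(idx)) next
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  dataset$fold <- fold
  dataset
}

#' Ensemble prediction for one window
#'
#' Averages the per-model scores: all `k` models for a window outside the
#' dataset; for a dataset window assigned to fold `j`, the `k - 1` scores
#' excluding model `j`'s.
#'
#' @param per_model_scores numeric vector of `k` scores in `[0, 1]`.
#' @param fold the window's fold (1-based), required when `in_dataset`.
#' @param in_dataset whether the window belongs to the training dataset.
#' @return The ensemble score.
#' @export
ensemble_score <- function(per_model_scores, fold = NA_integer_,
                           in_dataset = FALSE) {
  if (any(per_model_scores < 0 | per_model_scores > 1)) {
    stop("per-model scores must lie in [0, 1]")
  }
  if (in_dataset) {
    if (is.na(fold) || fold < 1 || fold > length(per_model_scores)) {
      stop("a dataset window needs a valid fold id")
    }
    mean(per_model_scores[-fold])
  } else {
    mean(per_model_scores)
  }
}

#' Write or read a window dataset as TSV
#'
#' Five columns: chrom, start, end (0-based half-open), label, fold.
#'
#' @param dataset data frame with the columns above.
#' @param path file path.
#' @return `write_window_dataset`: invisibly `path`; `read_window_dataset`:
#'   the data frame.
#' @export
write_window_dataset <- function(dataset, path) {
  cols <- intersect(c("chrom", "start", "end", "label", "fold"),
                    names(dataset))
  write.table(dataset[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_dataset
#' @export
read_window_dataset <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
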