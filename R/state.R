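## Normal-versus-cancer comparison of GQ pEP landscapes on state-specific
## cCRE tracks: per-state shares and two-set (Venn) partition counts. The
## GQ set and transcript annotation are shared across states; only the
## cCRE tracks differ.

#' GQ pEP pair share for one cCRE state
#'
#' Builds the pEP pair universe on this state's pELS elements and reports
#' the share of pairs with a GQ in both the promoter and the enhancer.
#'
#' @param state_ccres `GRanges` cCRE track with a `class` column.
#' @param tx_set the shared [transcript_set()].
#' @param gq_set the shared `GRanges` of GQ calls.
#' @param up,down promoter geometry.
#' @param flank GQ flagging flank (bp).
#' @return A list with `n_pairs`, `n_gq_both`, `share` and the flagged
#'   `pairs` table.
#' @export
state_pep_share <- function(state_ccres, tx_set, gq_set,
                            up = 1000L, down = 200L, flank = 0L) {
  pairs <- build_pep_pairs(tx_set, state_ccres, up = up, down = down)
  if (nrow(pairs) == 0L) stop("state has zero pEP pairs")
  pairs <- flag_gq(pairs, gq_set, flank)
  n_both <- sum(pairs$gq_in_promoter & pairs$gq_in_enhancer)
  list(n_pairs = nrow(pairs), n_gq_both = n_both,
       share = n_both / nrow(pairs), pairs = pairs)
}

#' Identity keys of GQ-bearing items in a pair universe
#'
#' Items are identified the way they are compared across states:
#' promoters by `transcript_id` (those with a promoter GQ), enhancers by
#' exact coordinates (those with an enhancer GQ), pairs by
#' `(transcript_id, enhancer coordinates)` (those with GQ on both sides).
#'
#' @param pairs a flagged pair table.
#' @param what one of `"promoter"`, `"enhancer"`, `"pair"`.
#' @return A character vector of unique keys.
#' @export
gq_item_keys <- function(pairs, what = c("pair", "promoter", "enhancer")) {
  what <- match.arg(what)
  if (is.null(pairs$gq_in_promoter)) stop("pairs must be flagged")
  switch(what,
    promoter = unique(pairs$transcript_id[pairs$gq_in_promoter]),
    enhancer = unique(pairs$enh_id[pairs$gq_in_enhancer]),
    pair = unique(paste(pairs$transcript_id, pairs$enh_id, sep = "|")[
      pairs$gq_in_promoter & pairs$gq_in_enhancer])
  )
}

#' Two-set partition counts
#'
#' Standard Venn partition of two key sets: items only in the first,
#' shared, and only in the second. Totals are conserved:
#' `|N| = n_normal_only + n_shared` and `|C| = n_cancer_only + n_shared`
#' (over unique keys).
#'
#' @param normal_items,cancer_items character vectors of item keys (e.g.
#'   from [gq_item_keys()]); duplicates are collapsed.
#' @return A named integer vector `(n_normal_only, n_shared,
#'   n_cancer_only)`.
#' @export
venn_partition <- function(normal_items, cancer_items) {
  n <- unique(normal_items)
  c_ <- unique(cancer_items)
  shared <- sum(n %in% c_)
  c(n_normal_only = length(n) - shared,
    n_shared = shared,
    n_cancer_only = length(c_) - shared)
}

#' Compare GQ pEP landscapes between two cCRE states
#'
#' Runs [state_pep_share()] on both tracks and partitions the GQ-bearing
#' promoters, enhancers and pairs between the states.
#'
#' @param normal_ccres,cancer_ccres the two state cCRE tracks.
#' @inheritParams state_pep_share
#' @return A list with the two share results (`normal`, `cancer`), a
#'   `fisher` 2x2 test on GQ-both versus other pair counts, and a `venn`
#'   list of partition counts per item type.
#' @export
compare_states <- function(normal_ccres, cancer_ccres, tx_set, gq_set,
                           up = 1000L, down = 200L, flank = 0L) {
  nr <- state_pep_share(normal_ccres, tx_set, gq_set, up, down, flank)
  cr <- state_pep_share(cancer_ccres, tx_set, gq_set, up, down, flank)
  tab <- matrix(c(nr$n_gq_both, nr$n_pairs - nr$n_gq_both,
                  cr$n_gq_both, cr$n_pairs - cr$n_gq_both),
                2L, 2L, byrow = TRUE)
  venn <- lapply(c(pair = "pair", promoter = "promoter",
                   enhancer = "enhancer"), function(w) {
    venn_partition(gq_item_keys(nr$pairs, w), gq_item_keys(cr$pairs, w))
  })
  list(normal = nr, cancer = cr, fisher = fisher_exact(tab), venn = venn)
}
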