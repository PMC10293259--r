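#' Assign multimapping reads to repeat families
#'
#' Each read carries one or more candidate alignments (family, alignment
#' score). Reads with a unique best-scoring family are assigned to it; ties
#' among best-scoring families are broken by a seeded uniform choice, so with
#' enough coverage reads are effectively averaged over the tied instances.
#' Assignment conserves reads: every read is assigned exactly once.
#'
#' @param hits Data frame with columns `read_id`, `family`, `score`.
#' @param seed Integer seed for tie-breaking.
#' @return Data frame `read_id`, `family` (one row per read, input read
#'   order).
#' @export
assign_multimappers <- function(hits, seed = 1) {
  stopifnot(all(c("read_id", "family", "score") %in% names(hits)))
  mx <- stats::ave(hits$score, hits$read_id, FUN = max)
  best <- hits[hits$score == mx, , drop = FALSE]
  .with_seed(seed, {
    shuffled <- best[sample(nrow(best)), , drop = FALSE]
    pick <- shuffled[!duplicated(shuffled$read_id), , drop = FALSE]
  })
  first_seen <- hits$read_id[!duplicated(hits$read_id)]
  pick <- pick[match(first_seen, pick$read_id), c("read_id", "family")]
  rownames(pick) <- NULL
  pick
}

#' Count assigned reads per family
#'
#' @param assignments Data frame from [assign_multimappers()] (or any with
#'   `family`), one row per read.
#' @param families Optional family universe (rows of the output); defaults to
#'   the families observed.
#' @return Named integer vector of raw counts.
#' @export
count_by_family <- function(assignments, families = NULL) {
  if (is.null(families)) families <- sort(unique(assignments$family))
  tab <- table(factor(assignments$family, levels = families))
  stats::setNames(as.integer(tab), families)
}

#' Normalize and filter a repeat count table
#'
#' Drops rRNA-class families, drops families below the minimum raw count
#' (`min_reads`, default 100) in any sample (`mode = "any"`, the conservative
#' reading of a per-sample rule; `"all"` drops only families failing in every
#' sample), and divides the remaining counts by the per-sample total aligned
#' reads.
#'
#' @param counts Matrix of raw counts (families x samples, rownames set).
#' @param totals Per-sample total aligned reads (genome-wide), recycled.
#' @param min_reads Minimum raw reads per family (default 100).
#' @param drop_classes Character vector of family class labels to drop
#'   (default `"rRNA"`).
#' @param classes Optional per-family class labels (defaults to rownames, so
#'   families literally named in `drop_classes` are dropped).
#' @param mode `"any"` (default) or `"all"` sample failure rule.
#' @return List: `normalized` (filtered counts / totals), `raw` (filtered raw
#'   counts), `dropped` (data frame of dropped families with reasons).
#' @export
normalize_and_filter <- function(counts, totals, min_reads = 100,
                                 drop_classes = "rRNA", classes = NULL,
                                 mode = c("any", "all")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), all(totals > 0))
  totals <- rep_len(totals, ncol(counts))
  if (is.null(classes)) classes <- rownames(counts)
  class_drop <- classes %in% drop_classes
  low <- if (mode == "any") apply(counts < min_reads, 1, any)
         else apply(counts < min_reads, 1, all)
  drop <- class_drop | low
  dropped <- data.frame(
    family = rownames(counts)[drop],
    reason = ifelse(class_drop[drop], "class",
                    sprintf("fewer than %d reads", min_reads)))
  kept <- counts[!drop, , drop = FALSE]
  list(normalized = sweep(kept, 2, totals, `/`), raw = kept,
       dropped = dropped)
}

#' Pairwise log2 repeat enrichment
#'
#' `log2(normalized_a / normalized_b)` per family. The minimum-read filter
#' guarantees positive counts, so no pseudocount is needed and the score is
#' finite and antisymmetric.
#'
#' @param norm_a,norm_b Normalized counts over the same filtered families.
#' @return Per-family log2 fold enrichment.
#' @export
repeat_enrichment <- function(norm_a, norm_b) {
  stopifnot(all(norm_a > 0), all(norm_b > 0),
            length(norm_a) == length(norm_b))
  log2(norm_a) - log2(norm_b)
}

#' Windowed profile over full-length repeat elements
#'
#' Scaled-body matrix over elements (default 250 body windows, the layout
#' used for full-length IAP profiles), optionally with fixed-width flank
#' windows. Restriction to uniquely mapped reads is the caller's choice via
#' the fragment mapping-quality filter before point generation.
#'
#' @param points Width-1 `GRanges`.
#' @param elements Stranded element `GRanges`, each at least `body_windows`
#'   bp long.
#' @param body_windows Number of scaled body windows (default 250).
#' @param flank_bp,flank_windows Optional flank layout (default none).
#' @return Matrix (elements x `2 * flank_windows + body_windows`).
#' @export
element_profile <- function(points, elements, body_windows = 250,
                            flank_bp = 0, flank_windows = 0) {
  .scaled_matrix(points, elements, flank_bp, flank_windows, body_windows)
}

#' Rank elements by an external signal into equal-count bins
#'
#' Elements are ordered by decreasing signal (e.g. H3.3 counts) and split
#' into `n_bins` equal-count bins; delegates to [bin_by_covariate()].
#'
#' @param signal Per-element signal (finite).
#' @param n_bins Number of bins (default 100).
#' @param values Optional per-element columns to average per bin.
#' @return As [bin_by_covariate()]; bin 1 holds the highest-signal elements.
#' @export
rank_elements_by_external_signal <- function(signal, n_bins = 100,
                                             values = NULL) {
  stopifnot(all(is.finite(signal)))
  bin_by_covariate(signal, n_bins, values = values, decreasing = TRUE)
}
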